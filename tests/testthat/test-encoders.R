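small_state <- function(seed = 0) {
  encoder_state(d_hidden = 16, depth = 2, n_heads = 2, d_proj = 8, seed = seed)
}

test_that("same seed and config reproduce bit-identical initial parameters", {
  a <- small_state(7)
  b <- small_state(7)
  expect_identical(a$params, b$params)
  c <- small_state(8)
  expect_false(identical(a$params, c$params))
})

test_that("a single-atom molecule is encoded without any message exchange", {
  st <- small_state()
  g <- smiles_to_atom_graph("C")
  emb <- encode_original(g, st)
  expect_length(emb$h_graph, 16)
  # no edges: the atom embedding is the transformed atom feature with zeroed
  # aggregation slots, and the readout equals that single row
  x <- cbind(g$atom_features, matrix(0, 1, 32))
  manual <- pmax(x %*% st$params$f.Wo + matrix(st$params$f.bo, 1), 0)
  expect_equal(emb$h_graph, as.numeric(manual), tolerance = 1e-12)
  expect_equal(emb$h_graph, as.numeric(emb$h_atoms[1, ]))
})

test_that("graph embeddings are invariant to atom and edge reindexing", {
  st <- small_state()
  set.seed(11)
  for (smi in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "CN1CCC[C@H]1c1cccnc1")) {
    g <- smiles_to_atom_graph(smi)
    ref <- encode_original(g, st)$h_graph
    perm <- sample(g$n_atoms)
    eperm <- sample(nrow(g$directed_bonds))
    gp <- permute_atom_graph(g, perm, eperm)
    got <- encode_original(gp, st)$h_graph
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("fragment embeddings are invariant to fragment reindexing", {
  st <- small_state()
  set.seed(12)
  fg <- brics_decompose("CC(=O)Oc1ccccc1C(=O)O")
  ref <- encode_augmented(fg, st)$h_graph
  expect_length(ref, 16)
  for (r in 1:3) {
    fp <- permute_fragment_graph(fg, sample(length(fg$fragments)))
    expect_equal(encode_augmented(fp, st)$h_graph, ref, tolerance = 1e-8)
  }
  # single-fragment graph: readout of the transformed fragment feature
  fg1 <- brics_decompose("CC")
  expect_length(encode_augmented(fg1, st)$h_graph, 16)
})

test_that("projection heads are two-layer ReLU maps", {
  st <- small_state()
  # zero input with zero-initialized biases gives zero output
  expect_equal(project(rep(0, 16), st, "g"), rep(0, 8))
  expect_length(project(rep(1, 16), st, "gt"), 8)
  expect_error(project(rep(1, 5), st, "g"), "input size")

  # hand-computed 2x2 example
  st2 <- encoder_state(d_hidden = 2, depth = 1, d_proj = 2, seed = 0)
  st2$params$g.W1 <- matrix(c(1, -1, 2, 0.5), 2, 2)
  st2$params$g.b1 <- matrix(c(0.1, -0.2), 1, 2)
  st2$params$g.W2 <- matrix(c(1, 0, -1, 1), 2, 2)
  st2$params$g.b2 <- matrix(c(0, 0.3), 1, 2)
  h <- c(1, 2)
  hidden <- pmax(c(1 * 1 + 2 * (-1) + 0.1, 1 * 2 + 2 * 0.5 - 0.2), 0) # (0, 2.8)
  manual <- c(hidden[1] * 1 + hidden[2] * 0, hidden[1] * (-1) + hidden[2] * 1 + 0.3)
  expect_equal(project(h, st2, "g"), manual)
})

test_that("every encoder parameter receives gradient under a dummy loss", {
  st <- small_state()
  ns <- asNamespace("fragprompt")
  pairs <- ns$augmented_pairs(c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "c1ccccc1O"),
                              st$config)
  tp <- ns$tape_new()
  pid <- ns$tp_params(tp, st$params)
  ho <- ns$forward_original(tp, pid, ns$batch_atom_graphs(pairs$original), st)
  ha <- ns$forward_augmented(tp, pid, ns$batch_fragment_graphs(pairs$augmented), st)
  zo <- ns$forward_projection(tp, pid, ho$h_id, "g")
  za <- ns$forward_projection(tp, pid, ha$h_id, "gt")
  zn <- ns$tp_rownorm(tp, ns$tp_rbind(tp, zo, za))
  loss <- ns$tp_ntxent(tp, ns$tp_tcross(tp, zn, zn), 0.1)
  grads <- ns$tp_backward(tp, loss)
  for (nm in names(st$params)) {
    expect_true(nm %in% names(grads), info = nm)
    expect_gt(max(abs(grads[[nm]])), 0)
  }
})

test_that("tape gradients agree with finite differences on a small model", {
  ns <- asNamespace("fragprompt")
  st <- encoder_state(d_hidden = 8, depth = 2, n_heads = 2, d_proj = 6, seed = 3)
  # aspirin guarantees reaction edges so the fragment message weights are used
  pairs <- ns$augmented_pairs(c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "C"), st$config)
  loss_fn <- function(params) {
    tp <- ns$tape_new()
    pid <- ns$tp_params(tp, params)
    ho <- ns$forward_original(tp, pid, ns$batch_atom_graphs(pairs$original), st)
    ha <- ns$forward_augmented(tp, pid, ns$batch_fragment_graphs(pairs$augmented), st)
    zo <- ns$forward_projection(tp, pid, ho$h_id, "g")
    za <- ns$forward_projection(tp, pid, ha$h_id, "gt")
    zn <- ns$tp_rownorm(tp, ns$tp_rbind(tp, zo, za))
    list(tp = tp, loss = ns$tp_ntxent(tp, ns$tp_tcross(tp, zn, zn), 0.1))
  }
  r <- loss_fn(st$params)
  f0 <- ns$tp_value(r$tp, r$loss)
  grads <- ns$tp_backward(r$tp, r$loss)
  set.seed(4)
  eps <- 1e-6
  for (nm in c("f.Wi", "f.Wc", "f.Wh", "f.Wo", "ft.We", "ft.WQ", "g.W1", "gt.W2")) {
    i <- sample(length(st$params[[nm]]), 1)
    p2 <- st$params
    p2[[nm]][i] <- p2[[nm]][i] + eps
    f1 <- ns$tp_value(loss_fn(p2)$tp, loss_fn(p2)$loss)
    expect_equal(grads[[nm]][i], (f1 - f0) / eps, tolerance = 1e-3)
  }
})

test_that("checkpoints round-trip bit-identically and guard the feature hash", {
  st <- small_state(5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(st, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, st$params)
  path2 <- tempfile(fileext = ".rds")
  save_checkpoint(back, path2)
  expect_identical(load_checkpoint(path2), back)

  # a tampered feature configuration must refuse to load
  bad <- st
  bad$config_hash <- "not-the-real-hash"
  save_checkpoint(bad, path)
  expect_error(load_checkpoint(path),
               class = "fragprompt_incompatible_checkpoint")
})
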