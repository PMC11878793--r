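test_that("smiles_to_atom_graph builds correct graphs for known molecules", {
  g1 <- smiles_to_atom_graph("C")
  expect_equal(g1$n_atoms, 1)
  expect_equal(g1$n_bonds, 0)
  expect_equal(nrow(g1$directed_bonds), 0)

  g2 <- smiles_to_atom_graph("CCO")
  expect_equal(g2$n_atoms, 3)
  expect_equal(g2$n_bonds, 2)
  expect_equal(nrow(g2$directed_bonds), 4)

  g3 <- smiles_to_atom_graph("c1ccccc1")
  expect_equal(g3$n_atoms, 6)
  expect_equal(g3$n_bonds, 6)
  # aromatic flag is the 41st feature column (after the 6 one-hot groups)
  arom_col <- sum(atom_feature_groups()[1:6]) + 1
  expect_equal(g3$atom_features[, arom_col], rep(1, 6))
})

test_that("malformed and empty SMILES raise parse errors", {
  expect_error(smiles_to_atom_graph("C("), class = "fragprompt_parse_error")
  expect_error(smiles_to_atom_graph(""), class = "fragprompt_parse_error")
})

test_that("every undirected bond yields exactly two directed entries", {
  for (smi in c("CCO", "CC(=O)Oc1ccccc1C(=O)O", "C1CCNCC1")) {
    g <- smiles_to_atom_graph(smi)
    expect_equal(nrow(g$directed_bonds), 2 * g$n_bonds)
    # rev is an involution pairing the two directions
    expect_equal(g$rev[g$rev], seq_len(nrow(g$directed_bonds)))
    expect_equal(g$directed_bonds$src[g$rev], g$directed_bonds$dst)
    expect_true(all(g$directed_bonds$src %in% seq_len(g$n_atoms)))
    expect_true(all(g$directed_bonds$dst %in% seq_len(g$n_atoms)))
  }
})

test_that("feature lengths are constant and expose the 8/4 attribute groups", {
  expect_length(atom_feature_groups(), 8)
  expect_length(bond_feature_groups(), 4)
  mols <- c("C", "CCO", "c1ccccc1", "CC(=O)N", "FC(F)(F)Br")
  for (smi in mols) {
    g <- smiles_to_atom_graph(smi)
    expect_equal(ncol(g$atom_features), sum(atom_feature_groups()))
    expect_equal(ncol(g$bond_features), sum(bond_feature_groups()))
  }
})

test_that("a SMILES and its canonical form yield isomorphic graphs", {
  pairs <- list(c("OCC", "CCO"),
                c("C1=CC=CC=C1", "c1ccccc1"),
                c("O=C(O)c1ccccc1", "c1ccccc1C(=O)O"))
  for (p in pairs) {
    g1 <- smiles_to_atom_graph(p[1])
    g2 <- smiles_to_atom_graph(p[2])
    sig <- function(g) sort(apply(g$atom_features, 1, paste, collapse = ","))
    expect_equal(sig(g1), sig(g2))
    deg <- function(g) sort(tabulate(g$directed_bonds$dst, g$n_atoms))
    expect_equal(deg(g1), deg(g2))
  }
})

test_that("scaffold split keeps whole scaffold groups together", {
  # all molecules share one benzene scaffold -> indivisible, all in train
  one_scaf <- paste0(c("C", "CC", "CCC", "N", "O", "CO", "CN", "Cl", "F", "CCO"),
                     "c1ccccc1")
  sp <- scaffold_split(one_scaf, 0.8, 0.1, 0.1)
  expect_equal(as.character(sp$split), rep("train", 10))

  # benzene-containing vs purely aliphatic molecules form distinct groups
  mixed <- c("Cc1ccccc1", "CCc1ccccc1", "CCCCCC", "CCCC")
  sp2 <- scaffold_split(mixed, frac_train = 0.5, frac_valid = 0.25, frac_test = 0.25)
  expect_equal(sp2$scaffold[1], sp2$scaffold[2])
  expect_equal(sp2$scaffold[3], sp2$scaffold[4])
  expect_false(sp2$scaffold[1] == sp2$scaffold[3])
})

test_that("scaffold split is a deterministic partition", {
  smiles <- load_fixture_corpus()[1:80]
  a <- scaffold_split(smiles)
  b <- scaffold_split(smiles)
  expect_identical(split_indices(a), split_indices(b))
  idx <- split_indices(a)
  expect_equal(sort(unname(unlist(idx))), 1:80)
  expect_length(intersect(idx$train, idx$valid), 0)
  expect_length(intersect(idx$train, idx$test), 0)
  expect_length(intersect(idx$valid, idx$test), 0)
  # every scaffold lands in exactly one fold
  folds <- tapply(a$split, a$scaffold, function(x) length(unique(x)))
  expect_true(all(folds == 1))
})

test_that("scaffold split rejects degenerate inputs", {
  expect_error(scaffold_split(c("C", "CC")), "at least 3")
  expect_error(scaffold_split(c("C", "CC", "CCC"), 0.5, 0.2, 0.2), "sum to 1")
})

test_that("classification metrics match the exhaustive pair-counting oracle", {
  m <- compute_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1),
                       task_kind = "binary_classification")
  expect_equal(unname(m$aggregate["roc_auc"]), 0.75)
  expect_equal(unname(m$aggregate["roc_auc"]),
               pairwise_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))

  # perfect ranking
  m2 <- compute_metrics(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1),
                        task_kind = "binary_classification")
  expect_equal(unname(m2$aggregate["roc_auc"]), 1.0)

  set.seed(42)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 2) # rounding forces occasional ties
    m3 <- compute_metrics(s, y, task_kind = "binary_classification")
    expect_equal(unname(m3$aggregate["roc_auc"]), pairwise_auc(s, y),
                 tolerance = 1e-10)
  }
})

test_that("regression metrics and label masking behave as specified", {
  y <- c(1.5, 2, -1, 0)
  m <- compute_metrics(y, y, task_kind = "regression")
  expect_equal(unname(m$aggregate[c("rmse", "mae")]), c(0, 0))

  p <- c(1, 2, 3, 4)
  yy <- c(2, 2, 1, 99)
  mask <- c(1, 1, 1, 0)
  m2 <- compute_metrics(p, yy, mask, task_kind = "regression")
  expect_equal(unname(m2$aggregate["rmse"]), sqrt(mean(c(1, 0, 4))))
  expect_equal(unname(m2$aggregate["mae"]), mean(c(1, 0, 2)))

  # single-class task after masking: warns and reports NA, not NaN
  expect_warning(
    m3 <- compute_metrics(c(0.2, 0.8, 0.5), c(1, 1, 0), mask = c(1, 1, 0),
                          task_kind = "binary_classification"),
    "single class"
  )
  expect_true(is.na(m3$per_task$value))
})

test_that("property datasets validate labels and masks", {
  ds <- property_dataset(
    tibble::tibble(smiles = c("C", "CC"), a = c(1, NA), b = c(0, 1)),
    task_kind = "binary_classification"
  )
  expect_equal(attr(ds, "n_tasks"), 2)
  lm <- fragprompt:::label_matrix(ds)
  expect_equal(lm$mask, cbind(a = c(1, 0), b = c(1, 1)))
  expect_error(
    property_dataset(tibble::tibble(smiles = "C", y = 2), "binary_classification"),
    "non-binary"
  )
})
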