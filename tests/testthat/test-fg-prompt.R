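test_that("the packaged table has 82 unique, compiling entries", {
  tab <- fg_table()
  expect_equal(nrow(tab), 82)
  expect_equal(anyDuplicated(tab$name), 0)
  expect_true(all(check_ok <- fragprompt:::check_smarts(tab$smarts)))
})

test_that("detection finds the expected groups with their atom sets", {
  # ethanol: the hydroxyl match is the oxygen (atom index 3, 1-based)
  d <- detect_functional_groups("CCO")
  hyd <- d[d$fg_name == "hydroxyl", ]
  expect_equal(nrow(hyd), 1)
  expect_equal(hyd$atoms[[1]], 3L)

  # methane matches nothing but the trivial methyl pattern is excluded by H count
  d2 <- detect_functional_groups("C")
  expect_equal(nrow(d2[d2$fg_name == "hydroxyl", ]), 0)

  # phenol against the reference SMARTS-matcher run (frozen): hydroxyl on the
  # oxygen, phenol on O+ipso carbon, phenyl on the six ring atoms
  d3 <- detect_functional_groups("Oc1ccccc1")
  expect_equal(d3$atoms[[which(d3$fg_name == "hydroxyl")]], 1L)
  expect_equal(d3$atoms[[which(d3$fg_name == "phenol")]], c(1L, 2L))
  expect_equal(d3$atoms[[which(d3$fg_name == "phenyl")]], 2:7)
  # deterministic ordering: by table entry index, then sorted atom indices
  expect_equal(d3$group_id, sort(d3$group_id))
})

test_that("molecules with no matches are a legal empty case", {
  tab <- fg_table()
  d <- detect_functional_groups("C", tab)
  d_methyl <- d[d$fg_name != "methyl", ]
  expect_equal(nrow(d_methyl), 0)
})

test_that("atom-signal fusion reduces to the single atom and is sum-linear", {
  pp <- prompt_params(n_groups = 82, d_hidden = 4, seed = 1)
  H <- matrix(rnorm(20), 5, 4)
  fg <- rnorm(4)
  # |Vi| = 1: sum and max both equal that atom's embedding
  v1 <- fuse_atom_signals(fg, 2, H, pp)
  manual <- pmax(matrix(c(fg, H[2, ], H[2, ]), 1) %*% pp$params$p.Wfuse +
                   pp$params$p.bfuse, 0)
  expect_equal(v1, as.numeric(manual))

  # Msum over a two-atom set is the sum of the single-atom sums;
  # Mmax is the elementwise maximum computed by direct comparison
  Vi <- c(1, 4)
  msum <- colSums(H[Vi, ])
  expect_equal(msum, colSums(H[1, , drop = FALSE]) + colSums(H[4, , drop = FALSE]))
  mmax3 <- apply(H[c(1, 3, 5), ], 2, max)
  direct <- pmax(pmax(H[1, ], H[3, ]), H[5, ])
  expect_equal(mmax3, direct)
  v2 <- fuse_atom_signals(fg, c(1, 3, 5), H, pp)
  manual2 <- pmax(matrix(c(fg, colSums(H[c(1, 3, 5), ]), direct), 1) %*%
                    pp$params$p.Wfuse + pp$params$p.bfuse, 0)
  expect_equal(v2, as.numeric(manual2))

  expect_error(fuse_atom_signals(fg, integer(0), H, pp), "Empty atom set")
})

test_that("prompt attention rows are probability vectors", {
  pp <- prompt_params(82, d_hidden = 8, seed = 2)
  set.seed(3)
  f_hat <- rbind(as.numeric(pp$params$p.fg0), matrix(rnorm(3 * 8), 3))
  out <- prompt_attention(f_hat, pp)
  expect_equal(unname(rowSums(out$attention)), rep(1, 4), tolerance = 1e-6)
  expect_equal(out$fg0_weights, out$attention[1, ])
  expect_equal(sum(out$fg0_weights), 1, tolerance = 1e-6)
  expect_equal(out$fg_prompt, out$f_fg[1, ])
  expect_true(all(is.finite(out$fg_prompt)))
})

test_that("with no functional groups the prompt depends on fg0 alone", {
  pp <- prompt_params(82, d_hidden = 8, seed = 2)
  out <- prompt_attention(matrix(pp$params$p.fg0, 1), pp)
  expect_equal(out$attention, matrix(1, 1, 1))
  again <- prompt_attention(matrix(pp$params$p.fg0, 1), pp)
  expect_identical(out$fg_prompt, again$fg_prompt)
})

test_that("the prompt vector is invariant to functional-group ordering", {
  pp <- prompt_params(82, d_hidden = 8, seed = 4)
  set.seed(5)
  rows <- matrix(rnorm(5 * 8), 5)
  f_hat <- rbind(as.numeric(pp$params$p.fg0), rows)
  ref <- prompt_attention(f_hat, pp)$fg_prompt
  for (r in 1:10) {
    perm <- sample(5)
    out <- prompt_attention(rbind(as.numeric(pp$params$p.fg0), rows[perm, ]), pp)
    expect_equal(out$fg_prompt, ref, tolerance = 1e-6)
  }
})

test_that("tying the value projection to the query weights is available", {
  ppt <- prompt_params(82, d_hidden = 8, seed = 4, tie_value_to_query = TRUE)
  ppf <- prompt_params(82, d_hidden = 8, seed = 4, tie_value_to_query = FALSE)
  set.seed(6)
  f_hat <- rbind(as.numeric(ppt$params$p.fg0), matrix(rnorm(16), 2))
  a <- prompt_attention(f_hat, ppt)
  b <- prompt_attention(f_hat, ppf)
  # same attention pattern, different values flowing through it
  expect_equal(a$attention, b$attention)
  expect_false(isTRUE(all.equal(a$fg_prompt, b$fg_prompt)))
})
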