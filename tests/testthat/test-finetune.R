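toy_head <- function() {
  list(W1 = matrix(c(1, 0, -1, 2, 0.5, 1, 0, -2), 4, 2),
       b1 = c(0.1, -0.1),
       W2 = matrix(c(1, -1), 2, 1),
       b2 = 0.2)
}

test_that("combine_and_predict concatenates, scales and matches manual arithmetic", {
  head <- toy_head()
  h <- c(1, 2)
  p <- c(0.5, -1)
  # alpha = 0 kills the prompt channel entirely
  y0 <- combine_and_predict(h, p, alpha = 0, head)
  y0b <- combine_and_predict(h, c(100, -100), alpha = 0, head)
  expect_equal(y0, y0b)
  # no_fg_prompt keeps the input size but zeroes the slot
  expect_equal(combine_and_predict(h, p, alpha = 1, head, no_fg_prompt = TRUE), y0)

  # hand-sized oracle: x = (1, 2, 1, -2) with alpha = 2
  x <- c(h, 2 * p)
  hidden <- pmax(as.numeric(x %*% toy_head()$W1) + c(0.1, -0.1), 0)
  manual <- sum(hidden * c(1, -1)) + 0.2
  expect_equal(combine_and_predict(h, p, alpha = 2, head), manual)
  expect_error(combine_and_predict(c(1, 2, 3), p, 1, head), "size mismatch")
})

test_that("the fine-tuning objective adds the scaled table penalty", {
  p <- matrix(c(0.3, -1, 2, 0.7), 2)
  y <- matrix(c(0, 1, 1, 0), 2)
  m <- matrix(1, 2, 2)
  ft <- matrix(c(1, 2, -3, 0.5), 2)
  base <- finetune_objective(p, y, m, ft, gamma = 0, "binary_classification")
  with_pen <- finetune_objective(p, y, m, ft, gamma = 0.01, "binary_classification")
  # elementwise sum-of-squares oracle
  expect_equal(with_pen - base, 0.01 * (1 + 4 + 9 + 0.25))

  # regression with perfect predictions and gamma = 0 is exactly zero
  expect_equal(finetune_objective(y, y, m, ft, 0, "regression"), 0)
  # masked-out entries do not contribute
  expect_equal(
    finetune_objective(p, y, matrix(c(1, 1, 0, 0), 2), ft, 0, "regression"),
    mean((p[, 1] - y[, 1])^2)
  )
  expect_error(finetune_objective(p, y, m * 0, ft, 0, "regression"), "masked")
})

test_that("fine-tuning is reproducible and honors ablation flags", {
  smiles <- load_fixture_corpus()[1:60]
  det <- detect_functional_groups(smiles)
  lab <- as.integer(smiles %in% unique(det$smiles[det$fg_name == "hydroxyl"]) |
                      smiles %in% unique(det$input_smiles[det$fg_name == "hydroxyl"]))
  ds <- property_dataset(tibble::tibble(smiles = smiles, label = lab),
                         "binary_classification")
  cfg <- finetune_config(epochs = 2, batch_size = 32, no_pretrain = TRUE,
                         d_hidden = 16)
  a <- suppressWarnings(finetune(ds, config = cfg, seeds = 0))
  b <- suppressWarnings(finetune(ds, config = cfg, seeds = 0))
  expect_identical(tidy(a)$value, tidy(b)$value)
  expect_identical(a$runs[[1]]$params, b$runs[[1]]$params)

  # the prompt-ablated model still trains, with an architecture of the same
  # shape (zeroed prompt slot)
  cfg2 <- finetune_config(epochs = 2, batch_size = 32, no_pretrain = TRUE,
                          d_hidden = 16, no_fg_prompt = TRUE)
  c0 <- suppressWarnings(finetune(ds, config = cfg2, seeds = 0))
  expect_equal(dim(c0$runs[[1]]$params$hp.W1), dim(a$runs[[1]]$params$hp.W1))
  expect_true(is.finite(tidy(c0)$value))

  preds <- predict(a, smiles[1:3])
  expect_equal(nrow(preds), 3)
  expect_true(all(preds$.pred_label >= 0 & preds$.pred_label <= 1))
})

test_that("an incompatible checkpoint is refused with a clear error", {
  st <- encoder_state(d_hidden = 8, depth = 1, seed = 0)
  st$config_hash <- "stale"
  ds <- property_dataset(tibble::tibble(smiles = c("C", "CC", "CCC", "CCO"),
                                        label = c(0, 1, 0, 1)),
                         "binary_classification")
  expect_error(finetune(ds, checkpoint = st, seeds = 0),
               class = "fragprompt_incompatible_checkpoint")
})

test_that("the training objective decreases early in every synthetic run", {
  fit <- get_full_fit()
  for (r in fit$runs) {
    h <- r$objective_history
    expect_lt(h[min(10, length(h))], h[1])
  }
})

test_that("explain reports only above-threshold rows with weights from the softmax", {
  fit <- get_full_fit()
  mols <- c("CCO", "Oc1ccccc1", "CCCC")
  rep0 <- explain(fit, mols, weight_threshold = 0)
  # full attention row sums to 1, so reported rows (excluding the task token)
  # sum to at most 1 per molecule
  sums <- tapply(rep0$weight, rep0$smiles, sum)
  expect_true(all(sums <= 1 + 1e-8))
  rep <- explain(fit, mols, weight_threshold = 0.15)
  if (nrow(rep) > 0) expect_true(all(rep$weight >= 0.15))
  # a molecule with no matches yields no rows
  expect_equal(nrow(explain(fit, "C", weight_threshold = 0)), 0)
})
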