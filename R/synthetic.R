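#' The packaged fixture corpus
#'
#' A curated list of 240 drug-like and enumerated small molecules spanning
#' diverse Bemis-Murcko scaffolds and over 30 functional-group classes;
#' every entry parses and BRICS-decomposes (the single-fragment fallback is
#' allowed for molecules without cleavable bonds).
#'
#' @return A character vector of canonical SMILES.
#' @export
load_fixture_corpus <- function() {
  path <- system.file("extdata", "fixture_corpus.smi", package = "fragprompt",
                      mustWork = TRUE)
  lines <- readLines(path, encoding = "UTF-8")
  lines[!startsWith(lines, "#") & nzchar(lines)]
}

#' Enumerate new molecules by BRICS recombination
#'
#' Decomposes the input molecules into BRICS fragments and reassembles
#' fragments at compatible link-type pairs, returning novel, valence-valid
#' (re-parseable) molecules. Deterministic given the seed.
#'
#' @param smiles Source molecules.
#' @param n Number of recombinants requested (fewer may be possible).
#' @param seed Integer seed.
#' @param max_heavy Heavy-atom cap for generated molecules.
#' @return Character vector of canonical SMILES not present in the input.
#' @export
brics_recombine <- function(smiles, n, seed = 0, max_heavy = 40) {
  res <- call_mol_helper("recombine", list(
    smiles = as.list(smiles), n = as.integer(n), seed = as.integer(seed),
    max_heavy = as.integer(max_heavy)
  ))
  vapply(res$smiles, identity, character(1))
}

#' Specify a synthetic property-prediction task
#'
#' Labels are defined through the same SMARTS table the model uses, so that
#' learning experiments isolate the training machinery rather than
#' chemistry disagreements. Classification rules label a molecule by the
#' presence of a named group (`"presence"`), or by the AND / XOR of two
#' groups; the regression rule is a linear combination of match counts plus
#' Gaussian noise.
#'
#' @param rule `"presence"`, `"and"`, `"xor"` or `"count_regression"`.
#' @param groups Character vector of functional-group names (1 for
#'   `presence`/`count_regression` with one term, 2 for `and`/`xor`;
#'   `count_regression` accepts any number).
#' @param coefficients Numeric coefficients for `count_regression`
#'   (recycled to `length(groups)`).
#' @param n_molecules Dataset size.
#' @param noise_sd Gaussian noise s.d. for regression labels.
#' @param seed Integer seed fixing the dataset exactly.
#' @return A `synthetic_task_spec` list.
#' @export
synthetic_task_spec <- function(rule = c("presence", "and", "xor", "count_regression"),
                                groups = "hydroxyl", coefficients = 2,
                                n_molecules = 800, noise_sd = 0, seed = 1) {
  rule <- rlang::arg_match(rule)
  if (rule %in% c("and", "xor") && length(groups) != 2) {
    abort(sprintf("Rule '%s' needs exactly two groups.", rule))
  }
  structure(list(rule = rule, groups = groups,
                 coefficients = rep_len(coefficients, length(groups)),
                 n_molecules = as.integer(n_molecules),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_task_spec")
}

#' Generate a synthetic labelled dataset
#'
#' Samples molecules from the fixture corpus, expanding the pool by BRICS
#' recombination when `n_molecules` exceeds the corpus, and labels them with
#' the task rule applied to functional-group match counts. Classification
#' datasets are rebalanced to 30-70% positives by stratified sampling.
#' Deterministic given the task-spec seed.
#'
#' @param spec A [synthetic_task_spec()].
#' @param table A [fg_table()]; every rule group must appear in it.
#' @return A [property_dataset()] with a single `label` column.
#' @export
generate_dataset <- function(spec, table = fg_table()) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  missing <- setdiff(spec$groups, table$name)
  if (length(missing)) {
    abort(c("Rule groups absent from the functional-group table:",
            setNames(missing, rep("x", length(missing)))))
  }
  set.seed(spec$seed)
  pool <- load_fixture_corpus()
  n <- spec$n_molecules
  if (n > length(pool)) {
    extra <- brics_recombine(pool, n = 2L * (n - length(pool)), seed = spec$seed)
    pool <- unique(c(pool, extra))
  }
  counts <- fg_rule_counts(pool, spec$groups, table)
  if (spec$rule == "count_regression") {
    take <- sample(pool, n, replace = n > length(pool))
    y <- as.numeric(counts[take, , drop = FALSE] %*% spec$coefficients)
    if (spec$noise_sd > 0) y <- y + rnorm(n, sd = spec$noise_sd)
    return(property_dataset(tibble::tibble(smiles = take, label = y),
                            task_kind = "regression"))
  }
  lab <- switch(spec$rule,
    presence = as.integer(counts[, 1] > 0),
    and = as.integer(counts[, 1] > 0 & counts[, 2] > 0),
    xor = as.integer(xor(counts[, 1] > 0, counts[, 2] > 0))
  )
  pos <- pool[lab == 1]
  neg <- pool[lab == 0]
  target <- min(max(length(pos) / length(pool), 0.3), 0.7)
  n_pos <- round(n * target)
  n_neg <- n - n_pos
  if (length(pos) == 0 || length(neg) == 0) {
    abort("Rule produces a single class on the molecule pool; cannot build a dataset.")
  }
  take_pos <- sample(pos, n_pos, replace = n_pos > length(pos))
  take_neg <- sample(neg, n_neg, replace = n_neg > length(neg))
  smiles <- c(take_pos, take_neg)
  y <- c(rep(1L, n_pos), rep(0L, n_neg))
  ord <- sample(length(smiles))
  property_dataset(tibble::tibble(smiles = smiles[ord], label = y[ord]),
                   task_kind = "binary_classification")
}

# match-count matrix (molecules x rule groups)
fg_rule_counts <- function(smiles, groups, table) {
  det <- detect_functional_groups(smiles, table)
  out <- matrix(0L, length(smiles), length(groups),
                dimnames = list(smiles, groups))
  for (k in seq_along(groups)) {
    hits <- det[det$fg_name == groups[k], ]
    if (nrow(hits) > 0) {
      tab <- table(hits$input_smiles)
      out[names(tab), k] <- as.integer(tab)
    }
  }
  out
}
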