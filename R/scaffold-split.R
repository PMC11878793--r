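#' Scaffold-based dataset splitting
#'
#' Groups molecules by Bemis-Murcko scaffold (ring systems plus linkers,
#' side chains removed) and assigns whole scaffold groups to train, then
#' validation, then test, so no scaffold straddles a partition boundary.
#' Groups are taken largest first, ties broken by lexicographic scaffold
#' string; acyclic molecules share the empty scaffold and therefore travel
#' together. With `deterministic = TRUE` (default) the split is a function
#' only of the dataset and the fractions; otherwise scaffold groups are
#' assigned in a random order.
#'
#' @param data A data frame with a `smiles` column (e.g. a
#'   [property_dataset()]) or a character vector of SMILES.
#' @param frac_train,frac_valid,frac_test Positive fractions summing to 1.
#' @param deterministic Logical; see above.
#' @return A `scaffold_split` tibble with columns `index`, `smiles`,
#'   `scaffold`, `split` (factor train/valid/test); fractions stored as an
#'   attribute. Use [split_indices()] for the three index sets.
#' @export
scaffold_split <- function(data, frac_train = 0.8, frac_valid = 0.1,
                           frac_test = 0.1, deterministic = TRUE) {
  smiles <- if (is.data.frame(data)) data$smiles else data
  n <- length(smiles)
  if (n < 3) abort("Scaffold splitting needs at least 3 molecules.")
  fr <- c(frac_train, frac_valid, frac_test)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-6) {
    abort("Fractions must be positive and sum to 1.")
  }
  info <- mol_info(smiles)
  require_parsed(info, smiles)
  scaf <- vapply(info, function(x) x$scaffold, character(1))
  groups <- split(seq_len(n), scaf)
  sizes <- lengths(groups)
  ord <- if (deterministic) {
    # radix = C-locale byte order, so the tie-break is locale-independent
    order(-sizes, names(groups), method = "radix")
  } else {
    sample(seq_along(groups))
  }
  groups <- groups[ord]
  n_train <- frac_train * n
  n_valid <- frac_valid * n
  assignment <- character(n)
  got_train <- got_valid <- 0L
  for (g in groups) {
    if (got_train < n_train) {
      assignment[g] <- "train"
      got_train <- got_train + length(g)
    } else if (got_valid < n_valid) {
      assignment[g] <- "valid"
      got_valid <- got_valid + length(g)
    } else {
      assignment[g] <- "test"
    }
  }
  structure(tibble::tibble(
    index = seq_len(n), smiles = smiles, scaffold = scaf,
    split = factor(assignment, levels = c("train", "valid", "test"))
  ), fractions = fr, class = c("scaffold_split", class(tibble::tibble())))
}

#' @rdname scaffold_split
#' @param x A `scaffold_split`.
#' @return `split_indices()` returns a list of integer vectors `train`,
#'   `valid`, `test` partitioning the dataset indices.
#' @export
split_indices <- function(x) {
  stopifnot(inherits(x, "scaffold_split"))
  lapply(split(x$index, x$split), as.integer)
}

#' Write a split manifest CSV
#'
#' @param x A `scaffold_split`.
#' @param path Output CSV path; columns `index`, `smiles`, `split`.
#' @export
write_split_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x[c("index", "smiles", "split")]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @method autoplot scaffold_split
#' @export
autoplot.scaffold_split <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$split)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$split, y = .data$n, fill = .data$split)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "molecules", title = "Scaffold split sizes") +
    ggplot2::theme_minimal()
}
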