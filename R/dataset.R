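#' Construct a labelled molecular property dataset
#'
#' Wraps a data frame with a `smiles` column and one or more label columns
#' into a `property_dataset` tibble. Empty cells / `NA` are treated as
#' missing labels and masked out of losses and metrics.
#'
#' @param data A data frame with a `smiles` column; all remaining columns
#'   (or `label_cols` if given) are task labels.
#' @param task_kind `"binary_classification"` or `"regression"`.
#' @param label_cols Optional character vector naming the label columns.
#' @return A `property_dataset` tibble with attributes `task_kind`,
#'   `n_tasks` and `label_cols`.
#' @export
property_dataset <- function(data, task_kind = c("binary_classification", "regression"),
                             label_cols = NULL) {
  task_kind <- rlang::arg_match(task_kind)
  data <- tibble::as_tibble(data)
  if (!"smiles" %in% names(data)) abort("`data` must have a `smiles` column.")
  if (is.null(label_cols)) label_cols <- setdiff(names(data), "smiles")
  if (length(label_cols) == 0) abort("At least one label column is required.")
  for (col in label_cols) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
    if (task_kind == "binary_classification") {
      bad <- !is.na(data[[col]]) & !data[[col]] %in% c(0, 1)
      if (any(bad)) abort(sprintf("Column `%s` has non-binary labels.", col))
    }
  }
  structure(data[c("smiles", label_cols)],
            task_kind = task_kind, n_tasks = length(label_cols),
            label_cols = label_cols,
            class = c("property_dataset", class(data)))
}

#' Read a property dataset from CSV
#'
#' The required column is `smiles`; every remaining column is a task label;
#' empty cells are missing labels.
#'
#' @param path CSV path.
#' @inheritParams property_dataset
#' @return A [property_dataset()].
#' @export
read_property_csv <- function(path, task_kind = c("binary_classification", "regression")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  property_dataset(df, task_kind = task_kind)
}

label_matrix <- function(dataset) {
  cols <- attr(dataset, "label_cols")
  y <- as.matrix(dataset[cols])
  mask <- 1 - is.na(y)
  y[is.na(y)] <- 0
  list(y = y, mask = mask)
}

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset> %d molecules, %d task(s), %s\n",
              nrow(x), attr(x, "n_tasks"), attr(x, "task_kind")))
  NextMethod()
}
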