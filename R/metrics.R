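#' Evaluation metrics for property prediction
#'
#' Classification tasks are scored by ROC-AUC per task (masked entries
#' excluded) with the mean over scoreable tasks as the aggregate; tasks left
#' with a single class after masking are skipped with a warning rather than
#' returning silent `NaN`. Regression tasks are scored by RMSE and MAE.
#'
#' @param predictions Numeric matrix (n x n_tasks) or vector of scores.
#' @param labels Numeric matrix or vector, aligned with `predictions`.
#' @param mask Optional 0/1 matrix; 0 marks missing labels. `NA` labels are
#'   masked automatically.
#' @param task_kind `"binary_classification"` or `"regression"`.
#' @return A list with `per_task` (tibble of task, metric, value) and
#'   `aggregate` (named numeric: `roc_auc`, or `rmse` and `mae`).
#' @export
compute_metrics <- function(predictions, labels, mask = NULL,
                            task_kind = c("binary_classification", "regression")) {
  task_kind <- rlang::arg_match(task_kind)
  predictions <- as.matrix(predictions)
  labels <- as.matrix(labels)
  stopifnot(all(dim(predictions) == dim(labels)))
  if (is.null(mask)) mask <- 1 - is.na(labels)
  mask <- as.matrix(mask) * (1 - is.na(labels))
  nt <- ncol(predictions)
  tasks <- colnames(labels) %||% paste0("task", seq_len(nt))
  rows <- list()
  for (t in seq_len(nt)) {
    keep <- mask[, t] > 0
    p <- predictions[keep, t]
    y <- labels[keep, t]
    if (task_kind == "binary_classification") {
      if (length(unique(y)) < 2) {
        warn(sprintf("Task `%s` has a single class after masking; skipped.", tasks[t]))
        auc <- NA_real_
      } else {
        auc <- as.numeric(pROC::auc(pROC::roc(
          response = y, predictor = p, levels = c(0, 1),
          direction = "<", quiet = TRUE
        )))
      }
      rows[[t]] <- tibble::tibble(task = tasks[t], metric = "roc_auc", value = auc)
    } else {
      rows[[t]] <- tibble::tibble(
        task = tasks[t],
        metric = c("rmse", "mae"),
        value = c(sqrt(mean((p - y)^2)), mean(abs(p - y)))
      )
    }
  }
  per_task <- dplyr::bind_rows(rows)
  aggregate <- if (task_kind == "binary_classification") {
    c(roc_auc = mean(per_task$value[per_task$metric == "roc_auc"], na.rm = TRUE))
  } else {
    c(rmse = mean(per_task$value[per_task$metric == "rmse"]),
      mae = mean(per_task$value[per_task$metric == "mae"]))
  }
  list(per_task = per_task, aggregate = aggregate)
}
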