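#' Configuration for fine-tuning
#'
#' Desk-scale defaults suitable for small datasets on one CPU. The
#' regularizer `gamma` multiplies the squared Frobenius norm of the
#' functional-group embedding table in the objective; `alpha_init` seeds the
#' learnable scalar that scales the prompt vector before concatenation.
#' Ablation flags: `no_pretrain` ignores any checkpoint and starts the
#' encoder from a seed initialization; `no_atom_message` zeroes the
#' atom-signal sum/max channels in the fusion step; `no_fg_prompt` replaces
#' the prompt slot with a zero vector of the same length.
#'
#' @param gamma Non-negative L2 penalty weight on the embedding table.
#' @param alpha_init Initial value of the learnable prompt scale.
#' @param epochs Maximum training epochs.
#' @param batch_size Molecules per batch.
#' @param learning_rate Adam learning rate.
#' @param patience Early-stopping patience on the validation metric
#'   (ROC-AUC maximized / RMSE minimized).
#' @param no_pretrain,no_atom_message,no_fg_prompt Independent ablation flags.
#' @param d_hidden,depth Encoder size used when training from scratch
#'   (ignored when a compatible checkpoint is supplied).
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(gamma = 1e-4, alpha_init = 1, epochs = 30,
                            batch_size = 64, learning_rate = 1e-3,
                            patience = 8, no_pretrain = FALSE,
                            no_atom_message = FALSE, no_fg_prompt = FALSE,
                            d_hidden = 64, depth = 3) {
  stopifnot(gamma >= 0, epochs >= 1, batch_size >= 1)
  structure(list(gamma = gamma, alpha_init = alpha_init,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 no_pretrain = isTRUE(no_pretrain),
                 no_atom_message = isTRUE(no_atom_message),
                 no_fg_prompt = isTRUE(no_fg_prompt),
                 d_hidden = as.integer(d_hidden), depth = as.integer(depth)),
            class = "finetune_config")
}

#' Combine a graph embedding with the scaled prompt and predict
#'
#' Concatenates the graph embedding with the alpha-scaled prompt vector and
#' applies the two-layer prediction head. With `no_fg_prompt` the prompt
#' slot is a zero vector of the same length, keeping the head input size
#' unchanged.
#'
#' @param h_graph Numeric vector (length `d_hidden`).
#' @param fg_prompt Numeric vector (length `d_f`).
#' @param alpha Scalar prompt scale.
#' @param head A list with `W1`, `b1`, `W2`, `b2`.
#' @param no_fg_prompt Zero out the prompt slot.
#' @return Numeric vector of per-task scores (logits for classification).
#' @export
combine_and_predict <- function(h_graph, fg_prompt, alpha, head,
                                no_fg_prompt = FALSE) {
  p <- if (no_fg_prompt) rep(0, length(fg_prompt)) else alpha * fg_prompt
  x <- matrix(c(h_graph, p), nrow = 1)
  if (ncol(x) != nrow(head$W1)) abort("Head input size mismatch.")
  z <- pmax(x %*% head$W1 + matrix(head$b1, 1), 0)
  as.numeric(z %*% head$W2 + matrix(head$b2, 1))
}

#' Fine-tuning objective
#'
#' Task loss (binary cross-entropy with logits for classification, mean
#' squared error for regression), with masked entries excluded, plus
#' `gamma` times the squared Frobenius norm of the functional-group
#' embedding table.
#'
#' @param predictions,labels Aligned numeric matrices (logits / targets).
#' @param mask 0/1 matrix marking observed labels.
#' @param f_table The embedding table matrix.
#' @param gamma Non-negative penalty weight.
#' @param task_kind `"binary_classification"` or `"regression"`.
#' @return A single number.
#' @export
finetune_objective <- function(predictions, labels, mask, f_table, gamma,
                               task_kind = c("binary_classification", "regression")) {
  task_kind <- rlang::arg_match(task_kind)
  predictions <- as.matrix(predictions)
  labels <- as.matrix(labels)
  mask <- as.matrix(mask)
  if (sum(mask) == 0) abort("All labels are masked; objective undefined.")
  task <- if (task_kind == "binary_classification") {
    sum(mask * (pmax(predictions, 0) - predictions * labels +
                  log1p(exp(-abs(predictions))))) / sum(mask)
  } else {
    sum(mask * (predictions - labels)^2) / sum(mask)
  }
  task + gamma * sum(f_table^2)
}

head_params <- function(d_in, d_hidden, n_tasks, seed) {
  set.seed(seed)
  list(hp.W1 = glorot(d_in, d_hidden), hp.b1 = zeros_row(d_hidden),
       hp.W2 = glorot(d_hidden, n_tasks), hp.b2 = zeros_row(n_tasks))
}

# forward pass for a molecule subset; returns logits (and attention info)
forward_predict <- function(tp, pid, graphs, fgs, state, prompt, config) {
  ob <- batch_atom_graphs(graphs)
  enc <- forward_original(tp, pid, ob, state)
  pr <- forward_prompt(tp, pid, fgs, enc$atom_id, ob$atom_offsets, prompt,
                       no_atom_message = config$no_atom_message)
  pslot <- if (config$no_fg_prompt) {
    tp_input(tp, matrix(0, ob$n_mols, prompt$d_f))
  } else {
    tp_scale_scalar(tp, pr$prompt_id, pid[["p.alpha"]])
  }
  hhat <- tp_cbind(tp, c(enc$h_id, pslot))
  z <- tp_relu(tp, tp_add_bias(tp, tp_matmul(tp, hhat, pid[["hp.W1"]]), pid[["hp.b1"]]))
  yhat <- tp_add_bias(tp, tp_matmul(tp, z, pid[["hp.W2"]]), pid[["hp.b2"]])
  list(yhat_id = yhat, prompt_info = pr)
}

predict_logits <- function(params, graphs, fgs, state, prompt, config,
                           chunk = 256L, want_attention = FALSE) {
  n <- length(graphs)
  out <- NULL
  att <- list()
  for (s0 in seq(1, n, by = chunk)) {
    take <- s0:min(s0 + chunk - 1, n)
    tp <- tape_new()
    pid <- tp_params(tp, params)
    fp <- forward_predict(tp, pid, graphs[take], fgs[take], state, prompt, config)
    out <- rbind(out, tp_value(tp, fp$yhat_id))
    if (want_attention) att[[length(att) + 1L]] <- fp$prompt_info
  }
  list(logits = out, attention = att)
}

#' Fine-tune a property prediction model with functional-group prompts
#'
#' Loads the pretrained original-graph encoder from a checkpoint (unless
#' `no_pretrain`), attaches the functional-group prompt generator and a
#' two-layer prediction head (Xavier-initialized), and trains encoder,
#' prompt table, task token, attention parameters, prompt scale and head
#' jointly on the scaffold-split training fold, early-stopping on the
#' validation metric. One independent run is trained per element of
#' `seeds`; test metrics are reported per run and aggregated as mean and
#' standard deviation.
#'
#' @param data A [property_dataset()].
#' @param checkpoint A `pretrain_result`, `encoder_state`, or a path saved
#'   with [save_checkpoint()]. `NULL` or `no_pretrain` trains from scratch.
#' @param config A [finetune_config()].
#' @param split Optional [scaffold_split()]; computed at 0.8/0.1/0.1
#'   deterministically when missing.
#' @param seeds Integer vector; one independent run per seed.
#' @param table A [fg_table()].
#' @param verbose Print per-epoch progress.
#' @return A `fragprompt_fit` with per-run models and metrics; see
#'   [tidy.fragprompt_fit()], [predict.fragprompt_fit()] and [explain()].
#' @export
finetune <- function(data, checkpoint = NULL, config = finetune_config(),
                     split = NULL, seeds = 0:2, table = fg_table(),
                     verbose = FALSE) {
  stopifnot(inherits(data, "property_dataset"))
  task_kind <- attr(data, "task_kind")
  if (is.null(split)) split <- scaffold_split(data)
  idx <- split_indices(split)
  lm <- label_matrix(data)
  base_state <- resolve_checkpoint(checkpoint, config)
  smiles <- data$smiles
  cfg_feat <- if (is.null(base_state)) feature_config() else base_state$config
  graphs <- atom_graphs(smiles, cfg_feat)
  fgs <- fg_match_list(smiles, table)
  runs <- lapply(seeds, function(seed) {
    finetune_run(seed, graphs, fgs, lm, idx, base_state, config, task_kind,
                 table, verbose)
  })
  metrics <- purrr::map2_dfr(runs, seeds, function(r, s) {
    dplyr::mutate(r$test_metrics$per_task, seed = s, .before = 1)
  })
  structure(list(runs = runs, seeds = seeds, metrics = metrics,
                 config = config, task_kind = task_kind,
                 label_cols = attr(data, "label_cols"), table = table,
                 split = split),
            class = "fragprompt_fit")
}

resolve_checkpoint <- function(checkpoint, config) {
  if (is.null(checkpoint) || config$no_pretrain) return(NULL)
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  if (inherits(checkpoint, "pretrain_result")) checkpoint <- checkpoint$state
  stopifnot(inherits(checkpoint, "encoder_state"))
  if (!identical(checkpoint$config_hash, config_hash(checkpoint$config))) {
    abort("Checkpoint feature configuration hash mismatch; refusing to load.",
          class = "fragprompt_incompatible_checkpoint")
  }
  checkpoint
}

finetune_run <- function(seed, graphs, fgs, lm, idx, base_state, config,
                         task_kind, table, verbose) {
  state <- if (is.null(base_state)) {
    encoder_state(d_hidden = config$d_hidden, depth = config$depth, seed = seed)
  } else {
    base_state
  }
  d <- state$d_hidden
  prompt <- prompt_params(nrow(table), d, seed = seed + 1L)
  head <- head_params(2 * d, d, ncol(lm$y), seed = seed + 2L)
  # trainable: shared original-graph encoder, prompt generator, scale, head
  params <- c(state$params[grep("^f\\.", names(state$params))],
              prompt$params, head,
              list(p.alpha = matrix(config$alpha_init, 1, 1)))
  frozen <- state$params[!grepl("^f\\.", names(state$params))]
  opt <- adam_new(params, lr = config$learning_rate)
  tr <- idx$train
  set.seed(seed)
  best <- list(metric = if (task_kind == "binary_classification") -Inf else Inf,
               params = params, epoch = 0L)
  waited <- 0L
  objective_history <- numeric(0)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr)
    batch_losses <- numeric(0)
    for (s0 in seq(1, length(ord), by = config$batch_size)) {
      take <- ord[s0:min(s0 + config$batch_size - 1, length(ord))]
      tp <- tape_new()
      pid <- tp_params(tp, params)
      fp <- forward_predict(tp, pid, graphs[take], fgs[take], state, prompt, config)
      y <- lm$y[take, , drop = FALSE]
      m <- lm$mask[take, , drop = FALSE]
      if (sum(m) == 0) next
      task_loss <- if (task_kind == "binary_classification") {
        tp_bce_logits(tp, fp$yhat_id, y, m)
      } else {
        tp_mse(tp, fp$yhat_id, y, m)
      }
      loss <- tp_add(tp, task_loss,
                     tp_scale_const(tp, tp_l2(tp, pid[["p.Ftable"]]), config$gamma))
      grads <- tp_backward(tp, loss)
      upd <- adam_step(opt, params, grads)
      opt <- upd$opt
      params <- upd$params
      batch_losses <- c(batch_losses, tp_value(tp, loss))
    }
    objective_history <- c(objective_history, mean(batch_losses))
    vm <- eval_fold(params, graphs, fgs, lm, idx$valid, state, prompt, config,
                    task_kind)
    # an unscoreable validation fold (e.g. single-class after masking)
    # yields NA: treat as no improvement rather than crashing
    improved <- !is.na(vm) && if (task_kind == "binary_classification") {
      vm > best$metric + 1e-12
    } else {
      vm < best$metric - 1e-12
    }
    # ties refresh the snapshot without resetting patience, so the kept
    # parameters are the most-trained ones among equally good epochs
    tied <- !is.na(vm) && !improved && if (task_kind == "binary_classification") {
      vm >= best$metric - 1e-12
    } else {
      vm <= best$metric + 1e-12
    }
    if (improved) {
      best <- list(metric = vm, params = params, epoch = ep)
      waited <- 0L
    } else {
      if (tied) best <- list(metric = best$metric, params = params, epoch = ep)
      waited <- waited + 1L
    }
    if (verbose) {
      message(sprintf("seed %d epoch %d: objective %.4f, valid %.4f",
                      seed, ep, objective_history[ep], vm))
    }
    if (waited >= config$patience) break
  }
  params <- best$params
  test_logits <- predict_logits(params, graphs[idx$test], fgs[idx$test],
                                state, prompt, config)$logits
  test_metrics <- suppressWarnings(compute_metrics(
    score_predictions(test_logits, task_kind), lm$y[idx$test, , drop = FALSE],
    lm$mask[idx$test, , drop = FALSE], task_kind
  ))
  state$params[names(params)[grepl("^f\\.", names(params))]] <-
    params[grepl("^f\\.", names(params))]
  state$params[names(frozen)] <- frozen
  list(seed = seed, params = params, state = state, prompt = prompt,
       best_epoch = best$epoch, valid_metric = best$metric,
       objective_history = objective_history, test_metrics = test_metrics)
}

score_predictions <- function(logits, task_kind) {
  if (task_kind == "binary_classification") stats::plogis(logits) else logits
}

eval_fold <- function(params, graphs, fgs, lm, fold, state, prompt, config,
                      task_kind) {
  logits <- predict_logits(params, graphs[fold], fgs[fold], state, prompt,
                           config)$logits
  met <- suppressWarnings(compute_metrics(
    score_predictions(logits, task_kind), lm$y[fold, , drop = FALSE],
    lm$mask[fold, , drop = FALSE], task_kind
  ))
  if (task_kind == "binary_classification") met$aggregate[["roc_auc"]] else met$aggregate[["rmse"]]
}

#' @export
print.fragprompt_fit <- function(x, ...) {
  ag <- glance(x)
  cat(sprintf("<fragprompt_fit> %s; %d run(s)\n", x$task_kind, length(x$runs)))
  print(ag)
  invisible(x)
}

#' Per-run and aggregate fine-tuning metrics
#'
#' `tidy()` returns one row per (run, task, metric); `glance()` aggregates
#' to mean and standard deviation per metric over the independent runs.
#'
#' @param x A `fragprompt_fit`.
#' @param ... Unused.
#' @method tidy fragprompt_fit
#' @export
tidy.fragprompt_fit <- function(x, ...) x$metrics

#' @rdname tidy.fragprompt_fit
#' @method glance fragprompt_fit
#' @export
glance.fragprompt_fit <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE),
                     n_runs = dplyr::n_distinct(.data$seed), .groups = "drop")
}

#' Predict properties for new molecules
#'
#' @param object A `fragprompt_fit`.
#' @param newdata Data frame with a `smiles` column, or a character vector.
#' @param run Which independent run's model to use (default: best
#'   validation metric).
#' @param ... Unused.
#' @return A tibble with `smiles` and one prediction column per task
#'   (probabilities for classification, raw values for regression).
#' @export
predict.fragprompt_fit <- function(object, newdata, run = NULL, ...) {
  smiles <- if (is.data.frame(newdata)) newdata$smiles else newdata
  r <- object$runs[[run %||% best_run(object)]]
  graphs <- atom_graphs(smiles, r$state$config)
  fgs <- fg_match_list(smiles, object$table)
  logits <- predict_logits(r$params, graphs, fgs, r$state, r$prompt,
                           object$config)$logits
  preds <- score_predictions(logits, object$task_kind)
  colnames(preds) <- paste0(".pred_", object$label_cols)
  dplyr::bind_cols(tibble::tibble(smiles = smiles), tibble::as_tibble(preds))
}

best_run <- function(object) {
  v <- vapply(object$runs, function(r) r$valid_metric, numeric(1))
  if (object$task_kind == "binary_classification") which.max(v) else which.min(v)
}

#' Per-molecule functional-group attention report
#'
#' For each molecule, reports every functional-group match whose
#' task-token attention weight is at or above `weight_threshold`, sorted by
#' descending weight. The weights are the task token's softmax row over
#' \{task token, matches\} exactly as used in the forward pass, so the full
#' row (including the task token's own weight) sums to 1 before filtering.
#' By default the weights are averaged over the fit's independent runs,
#' consistent with how test metrics are aggregated; pass `run` to inspect a
#' single run. Molecules with no matches yield no rows.
#'
#' @param object A `fragprompt_fit`.
#' @param molecules Data frame with a `smiles` column, or character vector.
#' @param weight_threshold Minimum reported weight (default 0.1).
#' @param run Which run's model to use; `NULL` (default) averages the
#'   attention weights over all independent runs.
#' @return A tibble with `smiles`, `fg_name`, `atom_indices` (0-based,
#'   semicolon-joined), `weight`.
#' @export
explain <- function(object, molecules, weight_threshold = 0.1, run = NULL) {
  stopifnot(inherits(object, "fragprompt_fit"))
  smiles <- if (is.data.frame(molecules)) molecules$smiles else molecules
  runs <- if (is.null(run)) object$runs else object$runs[run]
  graphs <- atom_graphs(smiles, runs[[1]]$state$config)
  fgs <- fg_match_list(smiles, object$table)
  rows <- list()
  for (i in seq_along(smiles)) {
    m <- length(fgs[[i]]$gid)
    if (m == 0) next
    wt <- rep(0, m)
    for (r in runs) {
      tp <- tape_new()
      pid <- tp_params(tp, r$params)
      fp <- forward_predict(tp, pid, graphs[i], fgs[i], r$state, r$prompt,
                            object$config)
      pr <- fp$prompt_info
      w <- pr$attention[pr$token_rows[1], pr$block == 1]
      wt <- wt + w[-1] / length(runs) # drop the task token's own weight
    }
    keep <- which(wt >= weight_threshold)
    if (length(keep) == 0) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      smiles = smiles[i],
      fg_name = object$table$name[fgs[[i]]$gid[keep]],
      atom_indices = vapply(fgs[[i]]$atoms[keep],
                            function(a) paste(a - 1L, collapse = ";"), character(1)),
      weight = wt[keep]
    ) |> dplyr::arrange(dplyr::desc(.data$weight))
  }
  if (length(rows) == 0) {
    return(tibble::tibble(smiles = character(), fg_name = character(),
                          atom_indices = character(), weight = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Plot a functional-group attention report
#'
#' @param report The tibble returned by [explain()].
#' @param top_n Show the `top_n` groups by mean weight.
#' @return A ggplot object.
#' @export
plot_fg_weights <- function(report, top_n = 15) {
  agg <- report |>
    dplyr::group_by(.data$fg_name) |>
    dplyr::summarise(mean_weight = mean(.data$weight), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_weight)) |>
    head(top_n)
  ggplot2::ggplot(agg, ggplot2::aes(x = stats::reorder(.data$fg_name, .data$mean_weight),
                                    y = .data$mean_weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean task-token attention weight") +
    ggplot2::theme_minimal()
}
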