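#' Normalized temperature-scaled contrastive (NT-Xent) loss
#'
#' Given N projected embeddings of the original view and the N matching
#' embeddings of the augmented view, every one of the 2N embeddings serves
#' as an anchor: its positive is its counterpart view and the denominator
#' runs over all other 2N-1 embeddings (cross-view and within-view
#' negatives; only the anchor itself is excluded). Similarity is cosine,
#' scaled by the temperature; the returned value is the arithmetic mean of
#' the 2N per-anchor losses. With N = 1 the denominator contains only the
#' positive and the loss is exactly 0.
#'
#' @param z,z_tilde Numeric matrices (N x d) of projected embeddings for the
#'   two views, aligned by row. No row may have zero norm.
#' @param temperature Positive temperature (default 0.1).
#' @return A single non-negative number.
#' @examples
#' z <- matrix(rnorm(8), 2)
#' nt_xent_loss(z, z + 0.1 * matrix(rnorm(8), 2))
#' @export
nt_xent_loss <- function(z, z_tilde, temperature = 0.1) {
  z <- as.matrix(z)
  z_tilde <- as.matrix(z_tilde)
  stopifnot(nrow(z) == nrow(z_tilde), ncol(z) == ncol(z_tilde), temperature > 0)
  Z <- rbind(z, z_tilde)
  rn <- sqrt(rowSums(Z^2))
  if (any(rn == 0)) abort("Zero-norm embedding: cosine similarity undefined.")
  Zn <- Z / rn
  S <- tcrossprod(Zn)
  n2 <- nrow(S)
  N <- n2 %/% 2L
  pos <- c(N + seq_len(N), seq_len(N))
  L <- S / temperature
  diag(L) <- -Inf
  mx <- apply(L, 1, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  mean(lse - L[cbind(seq_len(n2), pos)])
}

#' Configuration for contrastive pretraining
#'
#' Defaults are desk-scale (small corpora on one CPU): batch 32, 20 epochs,
#' Adam at 1e-3. For large unlabeled corpora the regime typically used with
#' this objective is batch 1024, 50 epochs, learning rate 3e-5; pass those
#' values explicitly to reproduce it. The temperature default is 0.1.
#'
#' @param temperature Positive temperature for [nt_xent_loss()].
#' @param batch_size Molecules per contrastive batch (>= 2 for a nonzero
#'   objective).
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed controlling shuffling (encoder initialization is
#'   governed by the `encoder_state` seed).
#' @return A `contrastive_config` list.
#' @export
contrastive_config <- function(temperature = 0.1, batch_size = 32, epochs = 20,
                               learning_rate = 1e-3, seed = 0) {
  stopifnot(temperature > 0, batch_size >= 1, epochs >= 1)
  structure(list(temperature = temperature, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "contrastive_config")
}

#' Contrastive pretraining over dual molecular views
#'
#' Builds the (original, fragment-reaction) view pair for every corpus
#' molecule, then minimizes the mean NT-Xent loss over shuffled batches with
#' Adam, training both encoders and both projection heads jointly. Fully
#' reproducible given the encoder seed and the config seed on one device.
#'
#' @param corpus Character vector of SMILES, or a data frame with a `smiles`
#'   column.
#' @param state An [encoder_state()]; its current parameters are the
#'   starting point.
#' @param config A [contrastive_config()].
#' @param log_file Optional path; per-epoch losses are appended as CSV.
#' @param verbose Print per-epoch loss.
#' @return A `pretrain_result`: list with the trained `state`, `config`,
#'   and `history` (tibble epoch/loss).
#' @export
pretrain <- function(corpus, state, config = contrastive_config(),
                     log_file = NULL, verbose = FALSE) {
  smiles <- if (is.data.frame(corpus)) corpus$smiles else corpus
  stopifnot(length(smiles) >= 1, inherits(state, "encoder_state"))
  pairs <- augmented_pairs(smiles, state$config)
  n <- length(smiles)
  bs <- config$batch_size
  if (bs > n) {
    warn(sprintf("Batch size %d exceeds corpus size %d; clamped.", bs, n))
    bs <- n
  }
  params <- state$params
  opt <- adam_new(params, lr = config$learning_rate)
  set.seed(config$seed)
  history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    idx <- sample(n)
    starts <- seq(1, n, by = bs)
    losses <- numeric(0)
    for (s0 in starts) {
      take <- idx[s0:min(s0 + bs - 1, n)]
      if (length(take) < 2) next
      tp <- tape_new()
      pid <- tp_params(tp, params)
      ob <- batch_atom_graphs(pairs$original[take])
      fb <- batch_fragment_graphs(pairs$augmented[take])
      ho <- forward_original(tp, pid, ob, state)
      ha <- forward_augmented(tp, pid, fb, state)
      zo <- forward_projection(tp, pid, ho$h_id, "g")
      za <- forward_projection(tp, pid, ha$h_id, "gt")
      zn <- tp_rownorm(tp, tp_rbind(tp, zo, za))
      sim <- tp_tcross(tp, zn, zn)
      loss <- tp_ntxent(tp, sim, config$temperature)
      grads <- tp_backward(tp, loss)
      upd <- adam_step(opt, params, grads)
      opt <- upd$opt
      params <- upd$params
      losses <- c(losses, tp_value(tp, loss))
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    if (!is.null(log_file)) {
      utils::write.table(
        data.frame(epoch = ep, loss = history[ep]), log_file, sep = ",",
        append = file.exists(log_file), col.names = !file.exists(log_file),
        row.names = FALSE
      )
    }
  }
  state$params <- params
  structure(list(state = state, config = config,
                 history = tibble::tibble(epoch = seq_len(config$epochs),
                                          loss = history)),
            class = "pretrain_result")
}

#' @export
print.pretrain_result <- function(x, ...) {
  cat(sprintf("<pretrain_result> %d epochs; first loss %.4f, final loss %.4f\n",
              nrow(x$history), x$history$loss[1],
              x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @method tidy pretrain_result
#' @export
tidy.pretrain_result <- function(x, ...) x$history

#' @method glance pretrain_result
#' @export
glance.pretrain_result <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history),
                 first_loss = x$history$loss[1],
                 final_loss = x$history$loss[nrow(x$history)],
                 temperature = x$config$temperature,
                 batch_size = x$config$batch_size)
}

#' @method autoplot pretrain_result
#' @export
autoplot.pretrain_result <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "mean NT-Xent loss",
                  title = "Contrastive pretraining") +
    ggplot2::theme_minimal()
}

# project all corpus molecules with both heads (used for separation checks
# and embedding export)
project_corpus <- function(smiles, state) {
  pairs <- augmented_pairs(smiles, state$config)
  tp <- tape_new()
  pid <- tp_params(tp, state$params)
  ho <- forward_original(tp, pid, batch_atom_graphs(pairs$original), state)
  ha <- forward_augmented(tp, pid, batch_fragment_graphs(pairs$augmented), state)
  zo <- forward_projection(tp, pid, ho$h_id, "g")
  za <- forward_projection(tp, pid, ha$h_id, "gt")
  list(z = tp_value(tp, zo), z_tilde = tp_value(tp, za))
}
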