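#' Save and load encoder checkpoints
#'
#' A checkpoint is a versioned container holding the encoder configuration
#' (sizes, depth, seed), all named parameter arrays and the hash of the
#' featurization configuration; loading verifies the hash so that a
#' checkpoint trained under different feature definitions fails loudly
#' rather than silently mis-featurizing. Saving and re-loading round-trips
#' bit-identically.
#'
#' @param x An `encoder_state` or `pretrain_result`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns an `encoder_state`.
#' @export
save_checkpoint <- function(x, path) {
  if (inherits(x, "pretrain_result")) x <- x$state
  stopifnot(inherits(x, "encoder_state"))
  saveRDS(list(format = "fragprompt_checkpoint", version = 1L, state = x), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "fragprompt_checkpoint")) {
    abort("Not a fragprompt checkpoint.", class = "fragprompt_incompatible_checkpoint")
  }
  state <- obj$state
  if (!identical(state$config_hash, config_hash(state$config))) {
    abort("Checkpoint feature configuration hash mismatch; refusing to load.",
          class = "fragprompt_incompatible_checkpoint")
  }
  state
}
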