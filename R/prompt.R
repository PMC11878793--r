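#' Initialize the functional-group prompt generator
#'
#' Creates the learnable embedding table (one row per functional-group
#' entry), the learnable task token `fg0`, the atom-signal fusion map, and
#' the single-block self-attention parameters (query/key/value maps, output
#' projection, layer norm). The prompt width `d_f` defaults to the encoder
#' hidden size so that the downstream concatenation is balanced.
#'
#' @param n_groups Number of table entries (82 for the packaged table).
#' @param d_hidden Atom-embedding size of the encoder.
#' @param d_f Prompt embedding size (default `d_hidden`).
#' @param seed Integer seed.
#' @param tie_value_to_query Use the query weights as the value projection
#'   (the literal printed form of the attention block); default `FALSE`,
#'   i.e. an independent value map.
#' @return A `prompt_params` list of named parameter matrices plus settings.
#' @export
prompt_params <- function(n_groups, d_hidden, d_f = d_hidden, seed = 0,
                          tie_value_to_query = FALSE) {
  set.seed(seed)
  params <- list(
    p.Ftable = glorot(n_groups, d_f),
    p.fg0 = glorot(1, d_f),
    p.Wfuse = glorot(d_f + 2 * d_hidden, d_f), p.bfuse = zeros_row(d_f),
    p.WQ = glorot(d_f, d_f), p.WK = glorot(d_f, d_f), p.WV = glorot(d_f, d_f),
    p.Wout = glorot(d_f, d_f),
    p.ln_g = matrix(1, 1, d_f), p.ln_b = zeros_row(d_f)
  )
  structure(list(params = params, n_groups = n_groups, d_hidden = d_hidden,
                 d_f = d_f, seed = seed,
                 tie_value_to_query = isTRUE(tie_value_to_query)),
            class = "prompt_params")
}

#' Fuse a functional-group embedding with its member-atom signals
#'
#' Concatenates the table embedding of a matched group with the sum and the
#' elementwise maximum of the final atom embeddings of its match atoms, then
#' applies the learnable fusion map followed by a rectifier.
#'
#' @param fg_embedding Numeric vector (length `d_f`): the group's table row.
#' @param atoms Non-empty integer vector of 1-based atom indices.
#' @param h_atoms Atom embedding matrix (n_atoms x d_hidden).
#' @param prompt A [prompt_params()].
#' @return Numeric vector of length `d_f`.
#' @export
fuse_atom_signals <- function(fg_embedding, atoms, h_atoms, prompt) {
  if (length(atoms) == 0) abort("Empty atom set: nothing to fuse.")
  H <- h_atoms[atoms, , drop = FALSE]
  msum <- colSums(H)
  mmax <- apply(H, 2, max)
  x <- matrix(c(fg_embedding, msum, mmax), nrow = 1)
  as.numeric(pmax(x %*% prompt$params$p.Wfuse + prompt$params$p.bfuse, 0))
}

#' Self-attention over the task token and fused functional-group rows
#'
#' Runs single-block self-attention over the (m+1) rows \{fg0, fused group
#' embeddings\}, applies the output projection and layer normalization, and
#' returns row 0 (the task token) as the molecule's prompt vector together
#' with the task token's attention distribution over all rows.
#'
#' @param f_hat Numeric matrix ((m+1) x d_f); row 1 must be the task token.
#' @param prompt A [prompt_params()].
#' @return A list with `f_fg` (the normalized output matrix), `fg_prompt`
#'   (row 1 of `f_fg`), `attention` (full (m+1) x (m+1) softmax matrix,
#'   rows summing to 1) and `fg0_weights` (its first row).
#' @export
prompt_attention <- function(f_hat, prompt) {
  f_hat <- as.matrix(f_hat)
  stopifnot(nrow(f_hat) >= 1)
  p <- prompt$params
  WV <- if (prompt$tie_value_to_query) p$p.WQ else p$p.WV
  Q <- f_hat %*% p$p.WQ
  K <- f_hat %*% p$p.WK
  V <- f_hat %*% WV
  S <- tcrossprod(Q, K) / sqrt(ncol(f_hat))
  mx <- apply(S, 1, max)
  E <- exp(S - mx)
  A <- E / rowSums(E)
  Ft <- A %*% V
  out <- Ft %*% p$p.Wout
  # row-wise layer normalization
  mu <- rowMeans(out)
  xc <- out - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + 1e-5)
  ffg <- (xc * inv) * matrix(p$p.ln_g, nrow(out), ncol(out), byrow = TRUE) +
    matrix(p$p.ln_b, nrow(out), ncol(out), byrow = TRUE)
  list(f_fg = ffg, fg_prompt = as.numeric(ffg[1, ]),
       attention = A, fg0_weights = as.numeric(A[1, ]))
}

## ---- batched tape forward for training ----

# Layout: molecule-major rows, the task token first, then that molecule's
# fused match rows. Returns ids plus the row bookkeeping needed to read the
# task-token attention back out.
forward_prompt <- function(tp, pid, mols_fg, atom_id, atom_offsets, prompt,
                           no_atom_message = FALSE) {
  n_mols <- length(mols_fg)
  d_f <- prompt$d_f
  m_counts <- vapply(mols_fg, function(x) length(x$gid), integer(1))
  total_matches <- sum(m_counts)
  fg0_tile <- tp_gather(tp, pid[["p.fg0"]], rep(1L, n_mols))
  if (total_matches > 0) {
    gid <- unlist(lapply(mols_fg, function(x) x$gid))
    match_mol <- rep(seq_len(n_mols), m_counts)
    flat_atoms <- integer(0)
    match_of_atom <- integer(0)
    mid <- 0L
    for (i in seq_len(n_mols)) {
      for (a in mols_fg[[i]]$atoms) {
        mid <- mid + 1L
        flat_atoms <- c(flat_atoms, a + atom_offsets[i])
        match_of_atom <- c(match_of_atom, rep(mid, length(a)))
      }
    }
    fg_emb <- tp_gather(tp, pid[["p.Ftable"]], gid)
    if (no_atom_message) {
      msum <- tp_input(tp, matrix(0, total_matches, prompt$d_hidden))
      mmax <- tp_input(tp, matrix(0, total_matches, prompt$d_hidden))
    } else {
      ga <- tp_gather(tp, atom_id, flat_atoms)
      msum <- tp_segsum(tp, ga, match_of_atom, total_matches)
      mmax <- tp_segmax(tp, ga, match_of_atom, total_matches)
    }
    fused <- tp_relu(tp, tp_add_bias(tp, tp_matmul(
      tp, tp_cbind(tp, c(fg_emb, msum, mmax)), pid[["p.Wfuse"]]), pid[["p.bfuse"]]))
    stacked <- tp_rbind(tp, fg0_tile, fused)
    # permute into molecule-major order with fg0 first per molecule
    row_mol <- c(seq_len(n_mols), match_mol)
    is_token <- c(rep(TRUE, n_mols), rep(FALSE, total_matches))
    perm <- order(row_mol, !is_token)
    fhat <- tp_gather(tp, stacked, perm)
    block <- row_mol[perm]
    token_rows <- which(is_token[perm])
  } else {
    fhat <- fg0_tile
    block <- seq_len(n_mols)
    token_rows <- seq_len(n_mols)
  }
  WVname <- if (prompt$tie_value_to_query) "p.WQ" else "p.WV"
  q <- tp_matmul(tp, fhat, pid[["p.WQ"]])
  k_ <- tp_matmul(tp, fhat, pid[["p.WK"]])
  v <- tp_matmul(tp, fhat, pid[[WVname]])
  sc <- tp_scale_const(tp, tp_tcross(tp, q, k_), 1 / sqrt(d_f))
  at <- tp_masked_softmax(tp, sc, block_mask(block))
  ft <- tp_matmul(tp, at, v)
  ffg <- tp_layernorm(tp, tp_matmul(tp, ft, pid[["p.Wout"]]),
                      pid[["p.ln_g"]], pid[["p.ln_b"]])
  fgp <- tp_gather(tp, ffg, token_rows)
  list(prompt_id = fgp, attention = tp_value(tp, at),
       token_rows = token_rows, block = block)
}

# per-molecule functional-group match structures from cached records
fg_match_list <- function(smiles, table) {
  info <- mol_info(smiles, table = table)
  require_parsed(info, smiles)
  lapply(info, function(rec) list(gid = rec$fg$gid, atoms = rec$fg$atoms))
}
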