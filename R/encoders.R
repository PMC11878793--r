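#' Initialize encoder parameters for both molecular views
#'
#' Builds the trainable state of the original-graph encoder `f` (a
#' communicative directed-edge message-passing network: edge messages are
#' aggregated per node by sum and elementwise max, combined through a
#' learnable map, and fed back into the edge updates), the
#' fragment-reaction-graph encoder `f_tilde` (fragment-node message passing
#' with reaction-edge features folded into messages, followed by multi-head
#' self-attention across fragments), and the two-layer ReLU projection heads
#' `g` and `g_tilde`. All weights use uniform Glorot initialization; the
#' same seed and configuration reproduce the state bit-identically.
#'
#' @param config A [feature_config()].
#' @param d_hidden Hidden size shared by both encoders (default 300).
#' @param depth Message-passing depth K of the original-graph encoder.
#' @param frag_depth Message-passing rounds on the fragment graph.
#' @param n_heads Attention heads for fragment aggregation (must divide
#'   `d_hidden`).
#' @param d_proj Output size of the projection heads.
#' @param seed Integer seed fixing the initialization.
#' @return An `encoder_state` list: `params` (named matrices), sizes, seed
#'   and the feature-configuration hash.
#' @export
encoder_state <- function(config = feature_config(), d_hidden = 300, depth = 3,
                          frag_depth = 2, n_heads = 2, d_proj = d_hidden,
                          seed = 0) {
  stopifnot(d_hidden %% n_heads == 0)
  fa <- atom_feature_length(config)
  fb <- bond_feature_length(config)
  ff <- fragment_feature_length(config)
  fr <- reaction_feature_length()
  d <- d_hidden
  set.seed(seed)
  params <- list(
    # original-graph encoder f
    f.Wi = glorot(fa + fb, d), f.bi = zeros_row(d),
    f.Wc = glorot(2 * d, d), f.bc = zeros_row(d),
    f.Wh = glorot(d, d),
    f.Wo = glorot(fa + 2 * d, d), f.bo = zeros_row(d),
    # fragment-graph encoder f_tilde
    ft.Wf = glorot(ff, d), ft.bf = zeros_row(d),
    ft.We = glorot(d + fr, d),
    ft.Wu = glorot(d, d),
    ft.WQ = glorot(d, d), ft.WK = glorot(d, d), ft.WV = glorot(d, d),
    ft.Wa = glorot(d, d),
    # projection heads
    g.W1 = glorot(d, d), g.b1 = zeros_row(d),
    g.W2 = glorot(d, d_proj), g.b2 = zeros_row(d_proj),
    gt.W1 = glorot(d, d), gt.b1 = zeros_row(d),
    gt.W2 = glorot(d, d_proj), gt.b2 = zeros_row(d_proj)
  )
  structure(list(
    params = params, d_hidden = d, depth = depth, frag_depth = frag_depth,
    n_heads = n_heads, d_proj = d_proj, seed = seed,
    config = config, config_hash = config_hash(config)
  ), class = "encoder_state")
}

#' @export
print.encoder_state <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<encoder_state> d_hidden=%d depth=%d (%s parameters, seed %d)\n",
              x$d_hidden, x$depth, format(np, big.mark = ","), x$seed))
  invisible(x)
}

## ---- batched graph containers ----

batch_atom_graphs <- function(graphs) {
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offs <- cumsum(c(0L, head(n_atoms, -1)))
  n_edges <- vapply(graphs, function(g) nrow(g$directed_bonds), integer(1))
  eoffs <- cumsum(c(0L, head(n_edges, -1)))
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  XB <- do.call(rbind, lapply(graphs, function(g) g$bond_features))
  src <- unlist(purrr::map2(graphs, offs, function(g, o) g$directed_bonds$src + o))
  dst <- unlist(purrr::map2(graphs, offs, function(g, o) g$directed_bonds$dst + o))
  rev <- unlist(purrr::map2(graphs, eoffs, function(g, o) g$rev + o))
  list(X = X, XB = XB,
       src = as.integer(src %||% integer(0)),
       dst = as.integer(dst %||% integer(0)),
       rev = as.integer(rev %||% integer(0)),
       mol_id = rep(seq_along(graphs), n_atoms),
       atom_offsets = offs, n_atoms = sum(n_atoms), n_mols = length(graphs))
}

batch_fragment_graphs <- function(fgraphs) {
  n_frag <- vapply(fgraphs, function(g) length(g$fragments), integer(1))
  offs <- cumsum(c(0L, head(n_frag, -1)))
  X <- do.call(rbind, lapply(fgraphs, function(g) g$fragment_features))
  src <- dst <- integer(0)
  XR <- matrix(0, 0, reaction_feature_length())
  rows <- list()
  for (i in seq_along(fgraphs)) {
    e <- fgraphs[[i]]$reaction_edges
    if (nrow(e) > 0) {
      # each undirected reaction edge feeds messages in both directions
      src <- c(src, e$u + offs[i], e$v + offs[i])
      dst <- c(dst, e$v + offs[i], e$u + offs[i])
      rf <- fgraphs[[i]]$reaction_features
      rows[[length(rows) + 1L]] <- rbind(rf, rf)
    }
  }
  if (length(rows)) XR <- do.call(rbind, rows)
  list(X = X, XR = XR, src = as.integer(src), dst = as.integer(dst),
       mol_id = rep(seq_along(fgraphs), n_frag),
       frag_offsets = offs, n_frag = sum(n_frag), n_mols = length(fgraphs))
}

# additive attention mask restricting attention to entries within one block
block_mask <- function(block_id) {
  same <- outer(block_id, block_id, `==`)
  mask <- matrix(-Inf, length(block_id), length(block_id))
  mask[same] <- 0
  mask
}

## ---- tape forward passes ----

# returns list(h_id = graph embeddings (n_mols x d), atom_id = atom matrix)
forward_original <- function(tp, pid, batch, state) {
  d <- state$d_hidden
  x_id <- tp_input(tp, batch$X)
  na <- batch$n_atoms
  if (length(batch$src) == 0) {
    zero_a <- tp_input(tp, matrix(0, na, 2 * d))
    hv <- tp_relu(tp, tp_add_bias(tp, tp_matmul(
      tp, tp_cbind(tp, c(x_id, zero_a)), pid[["f.Wo"]]), pid[["f.bo"]]))
    hg <- tp_segsum(tp, hv, batch$mol_id, batch$n_mols)
    return(list(h_id = hg, atom_id = hv))
  }
  xb_id <- tp_input(tp, batch$XB)
  e_in <- tp_cbind(tp, c(tp_gather(tp, x_id, batch$src), xb_id))
  h0 <- tp_relu(tp, tp_add_bias(tp, tp_matmul(tp, e_in, pid[["f.Wi"]]), pid[["f.bi"]]))
  he <- h0
  for (k in seq_len(state$depth)) {
    s <- tp_segsum(tp, he, batch$dst, na)
    mx <- tp_segmax(tp, he, batch$dst, na)
    q <- tp_relu(tp, tp_add_bias(tp, tp_matmul(
      tp, tp_cbind(tp, c(s, mx)), pid[["f.Wc"]]), pid[["f.bc"]]))
    msg <- tp_sub(tp, tp_gather(tp, q, batch$src), tp_gather(tp, he, batch$rev))
    he <- tp_relu(tp, tp_add(tp, h0, tp_matmul(tp, msg, pid[["f.Wh"]])))
  }
  s <- tp_segsum(tp, he, batch$dst, na)
  mx <- tp_segmax(tp, he, batch$dst, na)
  hv <- tp_relu(tp, tp_add_bias(tp, tp_matmul(
    tp, tp_cbind(tp, c(x_id, s, mx)), pid[["f.Wo"]]), pid[["f.bo"]]))
  hg <- tp_segsum(tp, hv, batch$mol_id, batch$n_mols)
  list(h_id = hg, atom_id = hv)
}

forward_augmented <- function(tp, pid, batch, state) {
  d <- state$d_hidden
  x_id <- tp_input(tp, batch$X)
  h0 <- tp_relu(tp, tp_add_bias(tp, tp_matmul(tp, x_id, pid[["ft.Wf"]]), pid[["ft.bf"]]))
  h <- h0
  if (length(batch$src) > 0) {
    xr_id <- tp_input(tp, batch$XR)
    for (k in seq_len(state$frag_depth)) {
      m_in <- tp_cbind(tp, c(tp_gather(tp, h, batch$src), xr_id))
      msg <- tp_matmul(tp, m_in, pid[["ft.We"]])
      agg <- tp_segsum(tp, msg, batch$dst, batch$n_frag)
      h <- tp_relu(tp, tp_add(tp, h0, tp_matmul(tp, agg, pid[["ft.Wu"]])))
    }
  }
  # multi-head self-attention across the fragments of each molecule
  mask <- block_mask(batch$mol_id)
  q <- tp_matmul(tp, h, pid[["ft.WQ"]])
  k_ <- tp_matmul(tp, h, pid[["ft.WK"]])
  v <- tp_matmul(tp, h, pid[["ft.WV"]])
  dh <- d %/% state$n_heads
  outs <- integer(state$n_heads)
  for (hd in seq_len(state$n_heads)) {
    cols <- ((hd - 1) * dh + 1):(hd * dh)
    qs <- tp_slice_cols(tp, q, cols)
    ks <- tp_slice_cols(tp, k_, cols)
    vs <- tp_slice_cols(tp, v, cols)
    sc <- tp_scale_const(tp, tp_tcross(tp, qs, ks), 1 / sqrt(dh))
    at <- tp_masked_softmax(tp, sc, mask)
    outs[hd] <- tp_matmul(tp, at, vs)
  }
  o <- tp_cbind(tp, outs)
  h <- tp_relu(tp, tp_add(tp, h, tp_matmul(tp, o, pid[["ft.Wa"]])))
  list(h_id = tp_segsum(tp, h, batch$mol_id, batch$n_mols))
}

forward_projection <- function(tp, pid, h_id, prefix) {
  z <- tp_relu(tp, tp_add_bias(tp, tp_matmul(tp, h_id, pid[[paste0(prefix, ".W1")]]),
                               pid[[paste0(prefix, ".b1")]]))
  tp_add_bias(tp, tp_matmul(tp, z, pid[[paste0(prefix, ".W2")]]),
              pid[[paste0(prefix, ".b2")]])
}

## ---- user-facing inference ----

#' Encode molecular graphs with the trained encoders
#'
#' `encode_original()` runs the directed-edge message-passing encoder on an
#' atom graph; `encode_augmented()` runs the fragment-attention encoder on a
#' fragment-reaction graph; `project()` applies a two-layer ReLU projection
#' head. All are deterministic given parameters and invariant to node
#' reindexing at the graph level.
#'
#' @param graph An `atom_graph` (or list of them).
#' @param state An [encoder_state()].
#' @return A `graph_embedding`: list with `h_graph` (length `d_hidden`
#'   vector) and `h_atoms` (n_atoms x d_hidden matrix). For
#'   `encode_augmented()`, `h_atoms` is `NULL`.
#' @export
encode_original <- function(graph, state) {
  stopifnot(inherits(graph, "atom_graph"), inherits(state, "encoder_state"))
  tp <- tape_new()
  pid <- tp_params(tp, state$params)
  out <- forward_original(tp, pid, batch_atom_graphs(list(graph)), state)
  structure(list(h_graph = as.numeric(tp_value(tp, out$h_id)),
                 h_atoms = tp_value(tp, out$atom_id)),
            class = "graph_embedding")
}

#' @rdname encode_original
#' @param fgraph A `fragment_graph`.
#' @export
encode_augmented <- function(fgraph, state) {
  stopifnot(inherits(fgraph, "fragment_graph"), inherits(state, "encoder_state"))
  tp <- tape_new()
  pid <- tp_params(tp, state$params)
  out <- forward_augmented(tp, pid, batch_fragment_graphs(list(fgraph)), state)
  structure(list(h_graph = as.numeric(tp_value(tp, out$h_id)), h_atoms = NULL),
            class = "graph_embedding")
}

#' @rdname encode_original
#' @param h A numeric vector (or `graph_embedding`) to project.
#' @param head Which projection head to use: `"g"` (original view) or
#'   `"gt"` (augmented view).
#' @export
project <- function(h, state, head = c("g", "gt")) {
  head <- rlang::arg_match(head)
  if (inherits(h, "graph_embedding")) h <- h$h_graph
  h <- matrix(h, nrow = 1)
  p <- state$params
  if (ncol(h) != nrow(p[[paste0(head, ".W1")]])) {
    abort("Embedding length does not match the projection head input size.")
  }
  z <- pmax(h %*% p[[paste0(head, ".W1")]] +
              matrix(p[[paste0(head, ".b1")]], 1), 0)
  as.numeric(z %*% p[[paste0(head, ".W2")]] + matrix(p[[paste0(head, ".b2")]], 1))
}
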