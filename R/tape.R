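# Minimal reverse-mode automatic differentiation over dense matrices.
# Ops force node-id arguments before touching tp$vals: nested op calls in
# argument position push onto the tape, so lazy promises must resolve first.
# A tape records one node per primitive op; backward closures capture the
# forward values they need. Scalars are length-1 numerics. This is the only
# machinery the encoders, the contrastive objective and the prompt module
# train through; no installed R package provides it.

tape_new <- function(capacity = 512L) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- vector("list", capacity)
  tp$bwd <- vector("list", capacity)
  tp$parents <- vector("list", capacity)
  tp$pname <- rep(NA_character_, capacity)
  tp$n <- 0L
  tp
}

tp_push <- function(tp, val, parents = integer(), bwd = NULL, pname = NA_character_) {
  i <- tp$n + 1L
  if (i > length(tp$vals)) {
    grow <- length(tp$vals)
    tp$vals <- c(tp$vals, vector("list", grow))
    tp$bwd <- c(tp$bwd, vector("list", grow))
    tp$parents <- c(tp$parents, vector("list", grow))
    tp$pname <- c(tp$pname, rep(NA_character_, grow))
  }
  tp$vals[[i]] <- val
  tp$bwd[[i]] <- bwd
  tp$parents[[i]] <- parents
  tp$pname[i] <- pname
  tp$n <- i
  i
}

tp_value <- function(tp, id) tp$vals[[id]]

tp_input <- function(tp, x) tp_push(tp, x)

tp_param <- function(tp, x, name) tp_push(tp, x, pname = name)

# registers every element of a named parameter list; returns a named id map
tp_params <- function(tp, params) {
  ids <- integer(length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- tp_param(tp, params[[nm]], nm)
  ids
}

tp_backward <- function(tp, loss_id) {
  n <- tp$n
  grads <- vector("list", n)
  grads[[loss_id]] <- 1
  for (i in seq.int(loss_id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    f <- tp$bwd[[i]]
    if (is.null(f)) next
    pg <- f(g)
    ps <- tp$parents[[i]]
    for (k in seq_along(ps)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      j <- ps[k]
      grads[[j]] <- if (is.null(grads[[j]])) gk else grads[[j]] + gk
    }
  }
  out <- list()
  idx <- which(!is.na(tp$pname[seq_len(n)]))
  for (i in idx) {
    if (is.null(grads[[i]])) next
    nm <- tp$pname[i]
    out[[nm]] <- if (is.null(out[[nm]])) grads[[i]] else out[[nm]] + grads[[i]]
  }
  out
}

## ---- primitive ops ----

tp_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_push(tp, A %*% B, c(a, b), function(g) list(g %*% t(B), crossprod(A, g)))
}

# A %*% t(B)
tp_tcross <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  tp_push(tp, tcrossprod(A, B), c(a, b), function(g) list(g %*% B, crossprod(g, A)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b), function(g) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b), function(g) list(g, -g))
}

# add a 1 x k bias row to every row of A
tp_add_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; bv <- tp$vals[[b]]
  tp_push(tp, A + matrix(bv, nrow(A), ncol(A), byrow = TRUE), c(a, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

tp_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

tp_scale_const <- function(tp, a, s) {
  force(a)
  tp_push(tp, tp$vals[[a]] * s, a, function(g) list(g * s))
}

# multiply a matrix by a learnable 1x1 scalar
tp_scale_scalar <- function(tp, a, s) {
  force(a); force(s)
  A <- tp$vals[[a]]; sv <- as.numeric(tp$vals[[s]])
  tp_push(tp, A * sv, c(a, s),
          function(g) list(g * sv, matrix(sum(g * A), 1, 1)))
}

tp_cbind <- function(tp, ids) {
  force(ids)
  vals <- tp$vals[ids]
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  tp_push(tp, do.call(cbind, vals), ids, function(g) {
    lapply(seq_along(ids), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

tp_rbind <- function(tp, a, b) {
  force(a); force(b)
  na <- nrow(tp$vals[[a]])
  nb <- nrow(tp$vals[[b]])
  tp_push(tp, rbind(tp$vals[[a]], tp$vals[[b]]), c(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[na + seq_len(nb), , drop = FALSE])
  })
}

tp_gather <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g) {
    list(as.matrix(Matrix::sparseMatrix(
      i = idx, j = seq_along(idx), x = 1, dims = c(nr, length(idx))
    ) %*% g))
  })
}

# per-group row sums; groups with no rows yield a zero row
tp_segsum <- function(tp, a, group, ngroups) {
  force(a)
  A <- tp$vals[[a]]
  n <- nrow(A)
  val <- if (n == 0) {
    matrix(0, ngroups, ncol(A))
  } else {
    as.matrix(Matrix::sparseMatrix(i = group, j = seq_len(n), x = 1,
                                   dims = c(ngroups, n)) %*% A)
  }
  tp_push(tp, val, a, function(g) {
    if (n == 0) return(list(matrix(0, 0, ncol(g))))
    list(g[group, , drop = FALSE])
  })
}

# per-group elementwise row maxima; empty groups yield a zero row.
# Gradient is routed to the argmax row per (group, column).
tp_segmax <- function(tp, a, group, ngroups) {
  force(a)
  A <- tp$vals[[a]]
  n <- nrow(A)
  k <- ncol(A)
  if (n == 0) {
    return(tp_push(tp, matrix(0, ngroups, k), a,
                   function(g) list(matrix(0, 0, k))))
  }
  members <- split(seq_len(n), factor(group, levels = seq_len(ngroups)))
  sizes <- lengths(members)
  M <- matrix(-Inf, ngroups, k)
  ARG <- matrix(0L, ngroups, k)
  for (d in seq_len(max(sizes))) {
    has <- which(sizes >= d)
    rows <- vapply(members[has], `[[`, integer(1), d)
    cand <- A[rows, , drop = FALSE]
    cur <- M[has, , drop = FALSE]
    arg <- ARG[has, , drop = FALSE]
    upd <- cand > cur
    cur[upd] <- cand[upd]
    rws <- matrix(rows, length(has), k)
    arg[upd] <- rws[upd]
    M[has, ] <- cur
    ARG[has, ] <- arg
  }
  M[sizes == 0, ] <- 0
  tp_push(tp, M, a, function(g) {
    sel <- ARG > 0L
    cols <- col(ARG)
    list(as.matrix(Matrix::sparseMatrix(
      i = ARG[sel], j = cols[sel], x = g[sel], dims = c(n, k)
    )))
  })
}

# softmax over rows of A + mask (mask is a constant matrix of 0 / -Inf);
# every row must keep at least one unmasked entry
tp_masked_softmax <- function(tp, a, mask = NULL) {
  force(a)
  A <- tp$vals[[a]]
  L <- if (is.null(mask)) A else A + mask
  mx <- apply(L, 1, max)
  E <- exp(L - mx)
  Y <- E / rowSums(E)
  tp_push(tp, Y, a, function(g) list(Y * (g - rowSums(g * Y))))
}

# row-wise layer normalization with learnable gain/bias (1 x k each)
tp_layernorm <- function(tp, a, gain, bias, eps = 1e-5) {
  force(a); force(gain); force(bias)
  A <- tp$vals[[a]]
  gv <- as.numeric(tp$vals[[gain]])
  k <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  val <- xhat * matrix(gv, nrow(A), k, byrow = TRUE) +
    matrix(as.numeric(tp$vals[[bias]]), nrow(A), k, byrow = TRUE)
  tp_push(tp, val, c(a, gain, bias), function(g) {
    dxhat <- g * matrix(gv, nrow(g), k, byrow = TRUE)
    dX <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dX, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

# rows scaled to unit L2 norm; errors on zero rows (cosine undefined)
tp_rownorm <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  rn <- sqrt(rowSums(A^2))
  if (any(rn == 0)) abort("Zero-norm embedding: cosine similarity undefined.")
  Y <- A / rn
  tp_push(tp, Y, a, function(g) list((g - Y * rowSums(g * Y)) / rn))
}

# NT-Xent loss from a 2N x 2N cosine-similarity matrix: every row is an
# anchor, its positive sits N rows away, the denominator runs over all other
# 2N-1 embeddings (self excluded via a -Inf diagonal).
tp_ntxent <- function(tp, s, tau) {
  force(s)
  S <- tp$vals[[s]]
  n2 <- nrow(S)
  N <- n2 %/% 2L
  pos <- c(N + seq_len(N), seq_len(N))
  L <- S / tau
  diag(L) <- -Inf
  mx <- apply(L, 1, max)
  lse <- mx + log(rowSums(exp(L - mx)))
  loss <- mean(lse - L[cbind(seq_len(n2), pos)])
  P <- exp(L - lse)
  tp_push(tp, loss, s, function(g) {
    D <- P
    D[cbind(seq_len(n2), pos)] <- D[cbind(seq_len(n2), pos)] - 1
    list(D * (g / (n2 * tau)))
  })
}

# mean binary cross-entropy with logits over observed entries
tp_bce_logits <- function(tp, a, y, mask) {
  force(a)
  X <- tp$vals[[a]]
  nobs <- sum(mask)
  val <- sum(mask * (pmax(X, 0) - X * y + log1p(exp(-abs(X))))) / nobs
  tp_push(tp, val, a, function(g) list(g * mask * (stats::plogis(X) - y) / nobs))
}

# mean squared error over observed entries
tp_mse <- function(tp, a, y, mask) {
  force(a)
  X <- tp$vals[[a]]
  nobs <- sum(mask)
  val <- sum(mask * (X - y)^2) / nobs
  tp_push(tp, val, a, function(g) list(g * 2 * mask * (X - y) / nobs))
}

# squared Frobenius norm
tp_l2 <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, sum(A^2), a, function(g) list(2 * g * A))
}

tp_slice_cols <- function(tp, a, cols) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  tp_push(tp, A[, cols, drop = FALSE], a, function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, cols] <- g
    list(out)
  })
}

## ---- parameter initialization and optimizer ----

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

zeros_row <- function(k) matrix(0, 1, k)

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}
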