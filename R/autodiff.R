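# Reverse-mode automatic differentiation on a flat tape.
#
# Values are dense double matrices. Each node records its value, parent nodes
# and a backward closure that accumulates gradients into the parents; the
# tape is replayed in reverse id order by ad_backward(). Nodes track whether
# any ancestor is a trainable parameter (need_grad); gradient work for pure
# constants (frozen features, adjacency matrices, inputs) is skipped. This is
# all the machinery the network modules need: affine maps, pointwise
# nonlinearities, broadcasted products, masked softmax, grouped pooling,
# im2col convolution, batch norm, dropout and a fused sigmoid/BCE loss.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$need_grad <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$need_grad, TRUE))
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_accum <- function(nd, g) {
  if (!nd$need_grad) return(invisible(NULL))
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  invisible(NULL)
}

# Leaf holding a constant (no gradient tracked).
ad_const <- function(tape, val) {
  nd <- ad_node(tape, as.matrix(val))
  nd$need_grad <- FALSE
  nd
}

# Leaf holding a trainable parameter; gradient collected after the sweep.
ad_param <- function(tape, val) {
  nd <- ad_node(tape, as.matrix(val))
  nd$need_grad <- TRUE
  nd$is_param <- TRUE
  nd
}

ad_backward <- function(tape, loss_node) {
  loss_node$grad <- matrix(1, nrow(loss_node$val), ncol(loss_node$val))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

## ---- arithmetic ----

ad_mm <- function(tape, a, b) {
  ad_node(tape, a$val %*% b$val, list(a, b), function(g) {
    if (a$need_grad) ad_accum(a, tcrossprod(g, b$val))
    if (b$need_grad) ad_accum(b, crossprod(a$val, g))
  })
}

ad_transpose <- function(tape, a) {
  ad_node(tape, t(a$val), list(a), function(g) ad_accum(a, t(g)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$val + b$val, list(a, b), function(g) {
    ad_accum(a, g); ad_accum(b, g)
  })
}

# a: n x m, bias: 1 x m broadcast over rows.
ad_add_bias <- function(tape, a, bias) {
  ad_node(tape, sweep(a$val, 2L, as.vector(bias$val), "+"), list(a, bias),
          function(g) {
            ad_accum(a, g)
            if (bias$need_grad) ad_accum(bias, matrix(colSums(g), 1L))
          })
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$val * s, list(a), function(g) ad_accum(a, g * s))
}

ad_mul <- function(tape, a, b) {
  ad_node(tape, a$val * b$val, list(a, b), function(g) {
    if (a$need_grad) ad_accum(a, g * b$val)
    if (b$need_grad) ad_accum(b, g * a$val)
  })
}

# a: n x m times row vector (1 x m), broadcast down rows.
ad_mul_rowvec <- function(tape, a, v) {
  vv <- as.vector(v$val)
  ad_node(tape, sweep(a$val, 2L, vv, "*"), list(a, v), function(g) {
    if (a$need_grad) ad_accum(a, sweep(g, 2L, vv, "*"))
    if (v$need_grad) ad_accum(v, matrix(colSums(g * a$val), 1L))
  })
}

# a: n x m times column vector (n x 1), broadcast across columns.
ad_mul_colvec <- function(tape, a, v) {
  vv <- as.vector(v$val)
  ad_node(tape, a$val * vv, list(a, v), function(g) {
    if (a$need_grad) ad_accum(a, g * vv)
    if (v$need_grad) ad_accum(v, matrix(rowSums(g * a$val), ncol = 1L))
  })
}

ad_relu <- function(tape, a) {
  keep <- a$val > 0
  ad_node(tape, a$val * keep, list(a), function(g) ad_accum(a, g * keep))
}

ad_sigmoid <- function(tape, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(tape, s, list(a), function(g) ad_accum(a, g * s * (1 - s)))
}

ad_cbind <- function(tape, nodes) {
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, vals), nodes, function(g) {
    for (i in seq_along(nodes))
      if (nodes[[i]]$need_grad)
        ad_accum(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_slice_cols <- function(tape, a, idx) {
  nc <- ncol(a$val)
  ad_node(tape, a$val[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), nc)
    ga[, idx] <- g
    ad_accum(a, ga)
  })
}

# Row gather (idx may repeat rows, e.g. broadcasting per-image rows over
# spatial positions); backward accumulates with rowsum().
ad_slice_rows <- function(tape, a, idx) {
  nr <- nrow(a$val)
  ad_node(tape, a$val[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nr, ncol(a$val))
    agg <- rowsum(g, group = idx)
    ga[as.integer(rownames(agg)), ] <- agg
    ad_accum(a, ga)
  })
}

## ---- softmax / pooling ----

# Row-wise softmax with exclusions. masked_out: logical matrix, TRUE where
# the entry is outside the neighbourhood; those entries get weight 0.
ad_masked_softmax <- function(tape, a, masked_out) {
  if (!is.logical(masked_out)) masked_out <- masked_out == 0
  m <- a$val
  m[masked_out] <- -Inf
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx[!is.finite(mx)] <- 0 # all-masked row (guarded upstream)
  e <- exp(m - mx)
  e[masked_out] <- 0
  s <- e / pmax(rowSums(e), .Machine$double.eps)
  ad_node(tape, s, list(a), function(g) {
    dot <- rowSums(g * s)
    ad_accum(a, s * (g - dot))
  })
}

# Row-wise maximum over columns -> n x 1, argmax routing in backward.
ad_rowmax <- function(tape, a) {
  w <- max.col(a$val, ties.method = "first")
  n <- nrow(a$val)
  val <- matrix(a$val[cbind(seq_len(n), w)], ncol = 1L)
  ad_node(tape, val, list(a), function(g) {
    ga <- matrix(0, n, ncol(a$val))
    ga[cbind(seq_len(n), w)] <- g
    ad_accum(a, ga)
  })
}

# Column means within row groups. groups: integer vector, one per row of a;
# result has one row per group level (sorted unique).
ad_group_mean <- function(tape, a, groups) {
  cnt <- table(groups)
  val <- rowsum(a$val, groups) / as.vector(cnt)
  dimnames(val) <- NULL
  lev <- sort(unique(groups))
  pos <- match(groups, lev)
  inv_n <- 1 / as.vector(cnt)[pos]
  ad_node(tape, val, list(a), function(g) {
    ad_accum(a, g[pos, , drop = FALSE] * inv_n)
  })
}

# Column-wise max within row groups, with argmax routing in the backward pass.
ad_group_max <- function(tape, a, groups) {
  lev <- sort(unique(groups))
  nc <- ncol(a$val)
  val <- matrix(0, length(lev), nc)
  amax <- matrix(0L, length(lev), nc)
  for (i in seq_along(lev)) {
    r <- which(groups == lev[i])
    sub <- a$val[r, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    amax[i, ] <- r[w]
    val[i, ] <- sub[cbind(w, seq_len(nc))]
  }
  ad_node(tape, val, list(a), function(g) {
    ga <- matrix(0, nrow(a$val), nc)
    # (group, column) argmax pairs are unique row/column combinations
    ga[cbind(as.vector(amax), rep(seq_len(nc), each = length(lev)))] <- as.vector(g)
    ad_accum(a, ga)
  })
}

## ---- im2col convolution support ----

# Gather rows of `a` into patch columns. idx: R_out x K matrix of row indices
# into a, NA meaning zero padding. Output: R_out x (K * ncol(a)), patch
# positions blocked contiguously.
ad_im2col <- function(tape, a, idx) {
  K <- ncol(idx)
  C <- ncol(a$val)
  R <- nrow(idx)
  val <- matrix(0, R, K * C)
  for (j in seq_len(K)) {
    rows <- idx[, j]
    ok <- !is.na(rows)
    block <- matrix(0, R, C)
    block[ok, ] <- a$val[rows[ok], , drop = FALSE]
    val[, ((j - 1L) * C + 1L):(j * C)] <- block
  }
  ad_node(tape, val, list(a), function(g) {
    if (!a$need_grad) return(invisible(NULL))
    ga <- matrix(0, nrow(a$val), C)
    for (j in seq_len(K)) {
      rows <- idx[, j]
      ok <- !is.na(rows)
      gb <- g[ok, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
      if (nrow(gb)) {
        agg <- rowsum(gb, group = rows[ok])
        ri <- as.integer(rownames(agg))
        ga[ri, ] <- ga[ri, ] + agg
      }
    }
    ad_accum(a, ga)
  })
}

## ---- batch normalisation ----

# Per-column batch norm. state: environment with running_mean / running_var.
# Training mode uses batch statistics and updates the running ones (momentum
# 0.1, population variance in the batch, unbiased in the running estimate);
# evaluation mode applies the stored affine map.
ad_batchnorm <- function(tape, a, gamma, beta, state, training, eps = 1e-5) {
  gv <- as.vector(gamma$val)
  if (training) {
    n <- nrow(a$val)
    mu <- colMeans(a$val)
    xc <- sweep(a$val, 2L, mu)
    v <- colMeans(xc^2)
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    state$running_mean <- 0.9 * state$running_mean + 0.1 * mu
    state$running_var <- 0.9 * state$running_var + 0.1 * v * n / max(n - 1L, 1L)
    val <- sweep(sweep(xhat, 2L, gv, "*"), 2L, as.vector(beta$val), "+")
    ad_node(tape, val, list(a, gamma, beta), function(g) {
      if (gamma$need_grad) ad_accum(gamma, matrix(colSums(g * xhat), 1L))
      if (beta$need_grad) ad_accum(beta, matrix(colSums(g), 1L))
      if (a$need_grad) {
        gx <- sweep(g, 2L, gv, "*")
        t1 <- sweep(gx, 2L, colMeans(gx))
        t2 <- sweep(xhat, 2L, colMeans(gx * xhat), "*")
        ad_accum(a, sweep(t1 - t2, 2L, istd, "*"))
      }
    })
  } else {
    istd <- 1 / sqrt(state$running_var + eps)
    xhat <- sweep(sweep(a$val, 2L, state$running_mean), 2L, istd, "*")
    val <- sweep(sweep(xhat, 2L, gv, "*"), 2L, as.vector(beta$val), "+")
    ad_node(tape, val, list(a, gamma, beta), function(g) {
      if (gamma$need_grad) ad_accum(gamma, matrix(colSums(g * xhat), 1L))
      if (beta$need_grad) ad_accum(beta, matrix(colSums(g), 1L))
      if (a$need_grad) ad_accum(a, sweep(sweep(g, 2L, gv, "*"), 2L, istd, "*"))
    })
  }
}

## ---- dropout ----

ad_dropout <- function(tape, a, rate, training) {
  if (!training || rate <= 0) return(a)
  keep <- matrix(stats::runif(length(a$val)) >= rate,
                 nrow(a$val), ncol(a$val)) / (1 - rate)
  ad_node(tape, a$val * keep, list(a), function(g) ad_accum(a, g * keep))
}

## ---- loss ----

# Mean binary cross-entropy of sigmoid(logits) against labels in {0,1}.
# Returns list(loss = scalar node, prob = probabilities). The gradient is
# routed directly to the logits ((p - y)/n), the exact BCE-on-sigmoid
# gradient in a numerically stable form.
ad_bce_sigmoid <- function(tape, logits, y) {
  z <- logits$val
  p <- 1 / (1 + exp(-z))
  n <- length(z)
  ll <- pmax(z, 0) - y * z + log1p(exp(-abs(z)))
  loss <- ad_node(tape, matrix(sum(ll) / n, 1L, 1L), list(logits), NULL)
  loss$backward <- function(g) ad_accum(logits, (p - y) / n * as.vector(g))
  list(loss = loss, prob = p)
}

## ---- parameter plumbing ----

# Mirror a nested list of matrices as parameter nodes on the tape.
ad_params <- function(tape, plist) {
  lapply(plist, function(x) {
    if (is.list(x)) ad_params(tape, x) else ad_param(tape, x)
  })
}

# Collect gradients from a structure produced by ad_params.
ad_grads <- function(pnodes) {
  lapply(pnodes, function(x) {
    if (is.list(x)) return(ad_grads(x))
    if (is.null(x$grad)) matrix(0, nrow(x$val), ncol(x$val)) else x$grad
  })
}
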