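# Parameter initialisation and reusable layer builders on the autodiff tape.

# He (ReLU fan-in) or Glorot initialisation for a dense layer.
init_linear <- function(fan_in, fan_out, act = c("relu", "linear", "sigmoid")) {
  act <- match.arg(act)
  sd <- if (act == "relu") sqrt(2 / fan_in) else sqrt(2 / (fan_in + fan_out))
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out),
       b = matrix(0, 1L, fan_out))
}

init_bn <- function(width) {
  list(gamma = matrix(1, 1L, width), beta = matrix(0, 1L, width))
}

bn_state_new <- function(width) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, width)
  st$running_var <- rep(1, width)
  st
}

# Convolution weights stored as a (k*k*C_in) x C_out matrix plus bias.
init_conv <- function(k, c_in, c_out, act = "relu") {
  p <- init_linear(k * k * c_in, c_out, act)
  names(p) <- c("W", "b")
  p
}

# x: parameter list(W, b); a: node. Affine map.
ly_linear <- function(tape, a, p) {
  ad_add_bias(tape, ad_mm(tape, a, ad_param_ref(tape, p, "W")),
              ad_param_ref(tape, p, "b"))
}

# When parameters are already nodes (from ad_params) use them directly;
# plain matrices are wrapped as constants (frozen evaluation).
ad_param_ref <- function(tape, p, name) {
  v <- p[[name]]
  if (is.environment(v)) v else ad_const(tape, v)
}

ly_linear_relu <- function(tape, a, p) ad_relu(tape, ly_linear(tape, a, p))

# ---- im2col index cache ----

conv_idx_cache <- new.env(parent = emptyenv())

# Row-index matrix mapping output positions to input rows for a kxk
# convolution over B stacked h x w maps (rows ordered image-major then
# row-major). stride >= 1; pad "same" keeps h x w (odd k), pad = 0 is valid.
conv_index <- function(h, w, k, B, stride = 1L, pad = (k - 1L) %/% 2L) {
  key <- paste(h, w, k, B, stride, pad, sep = "_")
  if (!is.null(conv_idx_cache[[key]])) return(conv_idx_cache[[key]])
  oh <- (h + 2L * pad - k) %/% stride + 1L
  ow <- (w + 2L * pad - k) %/% stride + 1L
  n_out <- oh * ow
  idx1 <- matrix(NA_integer_, n_out, k * k)
  pos <- 1L
  for (r in seq_len(oh)) for (c in seq_len(ow)) {
    r0 <- (r - 1L) * stride - pad
    c0 <- (c - 1L) * stride - pad
    col <- 1L
    for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
      rr <- r0 + dr + 1L; cc <- c0 + dc + 1L
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w)
        idx1[pos, col] <- (rr - 1L) * w + cc
      col <- col + 1L
    }
    pos <- pos + 1L
  }
  idx <- do.call(rbind, lapply(seq_len(B), function(b) {
    m <- idx1 + (b - 1L) * h * w
    m
  }))
  res <- list(idx = idx, oh = oh, ow = ow)
  conv_idx_cache[[key]] <- res
  res
}

# Tape convolution: a is (B*h*w) x C_in, returns (B*oh*ow) x C_out.
ly_conv2d <- function(tape, a, p, h, w, k, B, stride = 1L, pad = (k - 1L) %/% 2L) {
  ci <- conv_index(h, w, k, B, stride, pad)
  patches <- ad_im2col(tape, a, ci$idx)
  ad_add_bias(tape, ad_mm(tape, patches, ad_param_ref(tape, p, "W")),
              ad_param_ref(tape, p, "b"))
}

# Plain (no-gradient) convolution for the frozen backbone. x: (B*h*w) x C_in.
plain_conv2d <- function(x, p, h, w, k, B, stride = 1L, pad = (k - 1L) %/% 2L) {
  ci <- conv_index(h, w, k, B, stride, pad)
  K <- k * k; C <- ncol(x)
  P <- matrix(0, nrow(ci$idx), K * C)
  for (j in seq_len(K)) {
    rows <- ci$idx[, j]
    ok <- !is.na(rows)
    blk <- matrix(0, nrow(ci$idx), C)
    blk[ok, ] <- x[rows[ok], , drop = FALSE]
    P[, ((j - 1L) * C + 1L):(j * C)] <- blk
  }
  sweep(P %*% p$W, 2L, as.vector(p$b), "+")
}

# Expand a per-image row matrix (B x C) to (B*hw x C) by repeating each row
# hw times (image-major stacking), as a tape op.
ly_expand_rows <- function(tape, a, hw) {
  idx <- rep(seq_len(nrow(a$val)), each = hw)
  ad_slice_rows(tape, a, idx)
}
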