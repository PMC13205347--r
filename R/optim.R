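# Adam optimiser over nested parameter lists (matrix leaves).

adam_new <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else array(0, dim(x))
  }
  list(t = 0L, m = zeros(params), v = zeros(params))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  # fused bias-corrected step: p - alpha * m / (sqrt(v) + eps')
  alpha <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)
  epsp <- eps * sqrt(1 - beta2^t)
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- rec(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g * g
    list(p = p - alpha * m2 / (sqrt(v2) + epsp), m = m2, v = v2)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
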