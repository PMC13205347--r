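# Shared fixtures: small configurations, random graphs and a central
# finite-difference gradient checker.

# Reduced widths for fast unit tests (the projection widths stay at their
# architectural values only where a test asserts them).
tiny_cfg <- function() {
  cfg <- nmrmatch::default_config()
  cfg$graph$head_dim <- 4L
  cfg$graph$branch_width <- 8L
  cfg$graph$fused_width <- 12L
  cfg$graph$proj_hidden <- 16L
  cfg$graph$embed_dim <- 8L
  cfg$graph$dropout <- 0
  cfg$spectral$backbone <- "tiny"
  cfg$fusion$width <- 10L
  cfg$head$hidden <- 6L
  cfg
}

# Random connected graph with n nodes as a mol_graph-like structure for
# encoder tests (elements all carbon, random tree plus optional extra edge).
random_test_graph <- function(n, extra_edge_prob = 0.3) {
  bonds <- if (n > 1L) {
    data.frame(i = vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L),
               j = 2:n, order = 1L)
  } else data.frame(i = integer(), j = integer(), order = integer())
  if (n >= 4L && stats::runif(1) < extra_edge_prob) {
    a <- sample.int(n, 2L)
    adjacent <- any((bonds$i == min(a) & bonds$j == max(a)))
    if (!adjacent && min(a) != max(a))
      bonds <- rbind(bonds, data.frame(i = min(a), j = max(a), order = 1L))
  }
  nmrmatch::mol_graph(rep("C", n), bonds)
}

# Central-difference numerical gradient of f at x.
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Hop-distance matrix of a mol_graph (BFS).
hop_distances <- function(g) {
  n <- g$heavy_atom_count
  D <- matrix(Inf, n, n); diag(D) <- 0
  adj <- lapply(seq_len(n), function(i) integer())
  e <- g$edges
  for (r in seq_len(nrow(e))) adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Small backbone feature fixture: deterministic pseudo-random maps.
fake_feats <- function(B, hw = 16L, channels = 2048L, seed = 1) {
  set.seed(seed)
  lapply(seq_len(B), function(b) list(
    h = matrix(stats::rnorm(hw * channels, sd = 0.1), hw, channels),
    c = matrix(stats::rnorm(hw * channels, sd = 0.1), hw, channels)))
}
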