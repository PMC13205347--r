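# Graph encoder: neighbourhood-restricted attention, multi-scale branches,
# scale fusion, pooling and projection. Oracles are independently coded
# dense computations.

ns <- function(name) getFromNamespace(name, "nmrmatch")

test_that("attention over a singleton neighbourhood copies the neighbour value", {
  cfg <- tiny_cfg()
  cfg$graph$self_loops <- FALSE
  m <- build_model(cfg, "all", seed = 5)
  g <- mol_graph(c("C", "C"), data.frame(i = 1L, j = 2L, order = 1L))
  out <- multihead_graph_attention(g, m)
  for (k in seq_along(out$attn)) {
    A <- out$attn[[k]]
    expect_equal(A[1, 2], 1)
    expect_equal(A[2, 1], 1)
    expect_equal(diag(A), c(0, 0))
  }
  # output row = that neighbour's value vector, per head
  X <- g$node_features
  for (k in seq_len(cfg$graph$heads)) {
    hp <- m$params$graph$attn[[k]]
    V <- sweep(X %*% hp$v$W, 2L, as.vector(hp$v$b), "+")
    cols <- (k - 1L) * cfg$graph$head_dim + seq_len(cfg$graph$head_dim)
    expect_equal(out$H0[1, cols], V[2, ], tolerance = 1e-12)
  }
})

test_that("identical neighbour keys give uniform attention weights", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 6)
  # 5-cycle of identical atoms: every node's feature row is identical, so all
  # keys coincide and each neighbourhood (self + 2 ring neighbours) gets 1/3
  g <- mol_graph(rep("C", 5),
                 data.frame(i = c(1:4, 5L), j = c(2:5, 1L), order = 1L))
  out <- multihead_graph_attention(g, m)
  for (A in out$attn) {
    nz <- A[A > 0]
    expect_equal(unname(nz), rep(1 / 3, 15), tolerance = 1e-12)
  }
})

test_that("attention matches a dense softmax oracle on all small graphs", {
  set.seed(7)
  for (draw in 1:100) {
    n <- sample(2:6, 1)
    g <- random_test_graph(n)
    cfg <- tiny_cfg()
    m <- build_model(cfg, "all", seed = draw)
    out <- multihead_graph_attention(g, m)
    X <- g$node_features
    adj <- matrix(0, n, n); adj[g$edges] <- 1; diag(adj) <- 1
    for (k in sample(seq_len(cfg$graph$heads), 2)) {
      hp <- m$params$graph$attn[[k]]
      Q <- sweep(X %*% hp$q$W, 2, as.vector(hp$q$b), "+")
      K <- sweep(X %*% hp$k$W, 2, as.vector(hp$k$b), "+")
      V <- sweep(X %*% hp$v$W, 2, as.vector(hp$v$b), "+")
      S <- Q %*% t(K) / sqrt(cfg$graph$head_dim)
      H_or <- matrix(0, n, cfg$graph$head_dim)
      for (i in 1:n) {
        nb <- which(adj[i, ] == 1)
        w <- exp(S[i, nb] - max(S[i, nb]))
        w <- w / sum(w)
        H_or[i, ] <- colSums(V[nb, , drop = FALSE] * w)
      }
      cols <- (k - 1L) * cfg$graph$head_dim + seq_len(cfg$graph$head_dim)
      expect_equal(out$H0[, cols], H_or, tolerance = 1e-10)
    }
  }
})

test_that("attention rows are normalised over the neighbourhood and masked outside", {
  set.seed(8)
  for (draw in 1:25) {
    g <- random_test_graph(sample(2:8, 1))
    m <- build_model(tiny_cfg(), "all", seed = draw)
    out <- multihead_graph_attention(g, m)
    n <- g$heavy_atom_count
    adj <- matrix(0, n, n); adj[g$edges] <- 1; diag(adj) <- 1
    for (A in out$attn) {
      expect_equal(unname(rowSums(A)), rep(1, n), tolerance = 1e-6)
      expect_true(all(A[adj == 0] == 0))
    }
  }
})

test_that("message passing matches a dense normalised-adjacency oracle", {
  set.seed(9)
  for (draw in 1:100) {
    n <- sample(2:6, 1)
    g <- random_test_graph(n)
    cfg <- tiny_cfg()
    m <- build_model(cfg, "all", seed = 1000 + draw)
    tape <- ns("ad_tape")()
    bat <- ns("batch_graphs")(list(g))
    enc <- ns("graph_encoder_fwd")(tape, m$params$graph, bat, cfg, m$variant, FALSE)
    # oracle: explicit D^-1/2 (A+I) D^-1/2 products
    A <- matrix(0, n, n); A[g$edges] <- 1
    Ah <- A + diag(n)
    d <- 1 / sqrt(rowSums(Ah))
    An <- Ah * outer(d, d)
    H0 <- enc$H0$val
    p <- m$params$graph
    lin <- function(H, pl) sweep(H %*% pl$W, 2, as.vector(pl$b), "+")
    relu <- function(x) pmax(x, 0)
    expect_equal(enc$Hshort$val, relu(lin(An %*% H0, p$gcn0)), tolerance = 1e-10)
    expect_equal(enc$Hmid$val,
                 relu(lin(An %*% relu(lin(An %*% H0, p$gcn1)), p$gcn2)),
                 tolerance = 1e-10)
    Mn <- Ah / rowSums(Ah)
    sage <- function(H, pl) relu(lin(cbind(H, Mn %*% H), pl))
    expect_equal(enc$Hlong$val, sage(sage(sage(H0, p$sage1), p$sage2), p$sage3),
                 tolerance = 1e-10)
    expect_equal(enc$Hout$val,
                 lin(cbind(enc$Hshort$val, enc$Hmid$val, enc$Hlong$val), p$fuse),
                 tolerance = 1e-10)
  }
})

test_that("scale fusion reduces to a selector or zero map under crafted weights", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 10)
  bw <- cfg$graph$branch_width
  fw <- cfg$graph$fused_width
  g <- random_test_graph(4)
  # selector of the short branch
  W <- matrix(0, 3 * bw, fw)
  W[seq_len(bw), seq_len(min(bw, fw))] <- diag(1, bw, min(bw, fw))
  m$params$graph$fuse$W <- W
  m$params$graph$fuse$b <- matrix(0, 1, fw)
  tape <- ns("ad_tape")()
  enc <- ns("graph_encoder_fwd")(tape, m$params$graph, ns("batch_graphs")(list(g)),
                                 cfg, m$variant, FALSE)
  expect_equal(enc$Hout$val[, seq_len(min(bw, fw))], enc$Hshort$val, tolerance = 1e-12)
  m$params$graph$fuse$W <- 0 * W
  tape <- ns("ad_tape")()
  enc0 <- ns("graph_encoder_fwd")(tape, m$params$graph, ns("batch_graphs")(list(g)),
                                  cfg, m$variant, FALSE)
  expect_true(all(enc0$Hout$val == 0))
})

test_that("pooling concatenates per-dimension max and mean; projection widths hold", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 11)
  g <- random_test_graph(5)
  tape <- ns("ad_tape")()
  enc <- ns("graph_encoder_fwd")(tape, m$params$graph, ns("batch_graphs")(list(g)),
                                 cfg, m$variant, FALSE)
  fw <- cfg$graph$fused_width
  expect_equal(enc$fmol$val[1, seq_len(fw)], apply(enc$Hout$val, 2, max), tolerance = 1e-12)
  expect_equal(enc$fmol$val[1, fw + seq_len(fw)], colMeans(enc$Hout$val), tolerance = 1e-12)
  # single node: both halves equal that node's representation
  g1 <- mol_graph("C", data.frame(i = integer(), j = integer(), order = integer()))
  tape <- ns("ad_tape")()
  enc1 <- ns("graph_encoder_fwd")(tape, m$params$graph, ns("batch_graphs")(list(g1)),
                                  cfg, m$variant, FALSE)
  expect_equal(enc1$fmol$val[1, seq_len(fw)], enc1$fmol$val[1, fw + seq_len(fw)],
               tolerance = 1e-12)
  # architectural projection widths of the default configuration
  dcfg <- default_config()
  expect_equal(dcfg$graph$proj_hidden, 1500L)
  expect_equal(dcfg$graph$embed_dim, 128L)
  dm <- build_model(modifyList(dcfg, list(spectral = list(backbone = "tiny"))), "all", seed = 1)
  expect_equal(dim(dm$params$graph$proj1$W), c(2L * dcfg$graph$fused_width, 1500L))
  expect_equal(dim(dm$params$graph$proj2$W), c(1500L, 128L))
  emb <- encode_molecules(dm, g)
  expect_equal(dim(emb), c(1L, 128L))
})

test_that("the molecule embedding is invariant to node relabelling", {
  set.seed(12)
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 13)
  for (draw in 1:20) {
    n <- sample(3:9, 1)
    g <- random_test_graph(n)
    perm <- sample.int(n)
    b2 <- g$bond_orders
    b2$i <- perm[b2$i]; b2$j <- perm[b2$j]
    els <- character(n); els[perm] <- g$atom_elements
    gp <- mol_graph(els, b2)
    f1 <- encode_molecules(m, g)
    f2 <- encode_molecules(m, gp)
    expect_equal(f1, f2, tolerance = 1e-5)
  }
})

test_that("receptive fields respect the 2/3/4-hop locality bounds", {
  set.seed(14)
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 15)
  for (draw in 1:10) {
    n <- 10L
    g <- random_test_graph(n, extra_edge_prob = 0) # tree
    D <- hop_distances(g)
    i <- 1L
    far <- function(dmin) which(D[i, ] > dmin)
    run <- function(gg) {
      tape <- ns("ad_tape")()
      ns("graph_encoder_fwd")(tape, m$params$graph, ns("batch_graphs")(list(gg)),
                              cfg, m$variant, FALSE)
    }
    base <- run(g)
    for (dist_bound in list(c(2, "Hshort"), c(3, "Hmid"), c(4, "Hlong"))) {
      dmin <- as.integer(dist_bound[1]); field <- dist_bound[2]
      cand <- far(dmin)
      if (!length(cand)) next
      j <- cand[1]
      gg <- g
      gg$node_features[j, ] <- gg$node_features[j, ] + rnorm(ncol(gg$node_features))
      pert <- run(gg)
      expect_equal(base[[field]]$val[i, ], pert[[field]]$val[i, ], tolerance = 1e-10,
                   info = paste("branch", field, "node beyond", dmin, "hops"))
    }
  }
})

test_that("isolated nodes without self loops raise a configuration error", {
  cfg <- tiny_cfg()
  cfg$graph$self_loops <- FALSE
  m <- build_model(cfg, "all", seed = 16)
  g <- mol_graph("C", data.frame(i = integer(), j = integer(), order = integer()))
  expect_error(encode_molecules(m, g), "self_loops")
})
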