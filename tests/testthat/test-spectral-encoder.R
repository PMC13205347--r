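# Spectral branch: frozen backbone contract, 1x1 reduction, channel/spatial
# attention and cross-branch joint gating, each against straight-line oracles.

ns <- function(name) getFromNamespace(name, "nmrmatch")

sigm <- function(x) 1 / (1 + exp(-x))

make_model <- function(seed = 20, multiscale = TRUE) {
  cfg <- tiny_cfg()
  cfg$spectral$multiscale <- multiscale
  build_model(cfg, if (multiscale) "all" else "C", seed = seed)
}

rand_img <- function(seed) {
  set.seed(seed)
  array(runif(256 * 256 * 3), dim = c(256, 256, 3))
}

test_that("backbone features are 2048 channels with preserved spatial grid", {
  m <- make_model(21)
  f <- extract_backbone_features(m$backbone, rand_img(1), rand_img(2))
  hw <- ns("backbone_out_hw")(m$backbone)
  expect_equal(dim(f$h), c(hw * hw, 2048L))
  expect_equal(dim(f$c), c(hw * hw, 2048L))
  # 1x1 reduction: spatial rows unchanged, 16 channels
  tape <- ns("ad_tape")()
  red <- ns("ly_linear")(tape, ns("ad_const")(tape, f$h), m$params$spectral$h$reduce)
  expect_equal(dim(red$val), c(hw * hw, 16L))
})

test_that("wrong image sizes and trainable backbones are rejected", {
  m <- make_model(22)
  small <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_error(extract_backbone_features(m$backbone, small, small), "256x256")
  m$backbone$frozen <- FALSE
  expect_error(extract_backbone_features(m$backbone, rand_img(1), rand_img(2)), "frozen")
})

test_that("backbone output is bit-identical after a training step", {
  set.seed(23)
  ds <- generate_dataset(20, seed = 23, size_range = c(3L, 8L))
  cfg <- tiny_cfg()
  m <- build_model(cfg, "all", seed = 23)
  img <- ds$images[[1]]$h
  before <- ns("backbone_forward_one")(m$backbone, img)
  w_before <- m$backbone$weights
  feats <- prepare_features(m, ds)
  m2 <- train_model(m, ds, epochs = 1, seed = 23, feats = feats)
  after <- ns("backbone_forward_one")(m2$backbone, img)
  expect_identical(before, after)
  expect_identical(w_before, m2$backbone$weights)
})

test_that("CBAM channel weights follow the sigmoid identities", {
  m <- make_model(24)
  hw <- ns("backbone_out_hw")(m$backbone)
  C <- 16L
  # all-zero MLP: Mc = sigmoid(0) = 0.5 everywhere
  mz <- m
  mz$params$spectral$h$cbam$mlp1$W[] <- 0; mz$params$spectral$h$cbam$mlp1$b[] <- 0
  mz$params$spectral$h$cbam$mlp2$W[] <- 0; mz$params$spectral$h$cbam$mlp2$b[] <- 0
  set.seed(1)
  fmap <- matrix(rnorm(hw * hw * C), hw * hw, C)
  out <- cbam_enhance(mz, fmap, hw, hw, "h")
  expect_equal(as.vector(out$Mc), rep(0.5, C))
  # spatially constant map: GAP and GMP coincide so Mc = sigmoid(2 MLP(g))
  m2 <- make_model(25)
  cmap <- matrix(rep(rnorm(C), each = hw * hw), hw * hw, C)
  out2 <- cbam_enhance(m2, cmap, hw, hw, "h")
  p <- m2$params$spectral$h$cbam
  g <- matrix(cmap[1, ], 1)
  mlp <- function(x) pmax(x %*% p$mlp1$W + as.vector(p$mlp1$b)[col(x %*% p$mlp1$W)], 0) %*%
    p$mlp2$W + matrix(p$mlp2$b, 1)
  expect_equal(as.vector(out2$Mc), as.vector(sigm(2 * mlp(g))), tolerance = 1e-10)
})

test_that("CBAM matches an independent straight-line evaluation", {
  set.seed(26)
  for (draw in 1:20) {
    m <- make_model(100 + draw)
    h <- 4L; w <- 4L; C <- 16L
    fmap <- matrix(rnorm(h * w * C), h * w, C)
    out <- cbam_enhance(m, fmap, h, w, "h")
    p <- m$params$spectral$h$cbam
    # oracle: channel attention
    gap <- matrix(colMeans(fmap), 1)
    gmp <- matrix(apply(fmap, 2, max), 1)
    mlp <- function(x) pmax(x %*% p$mlp1$W + matrix(p$mlp1$b, 1), 0) %*% p$mlp2$W +
      matrix(p$mlp2$b, 1)
    Mc <- sigm(mlp(gap) + mlp(gmp))
    Fc <- sweep(fmap, 2, as.vector(Mc), "*")
    # oracle: spatial attention via explicit 7x7 convolution with zero padding
    avg_c <- rowMeans(Fc); max_c <- apply(Fc, 1, max)
    W7 <- p$spatial$W # (49*2) x 1, patch-major blocks of 2 channels
    ms_lin <- numeric(h * w)
    for (r in 1:h) for (cc in 1:w) {
      acc <- p$spatial$b[1, 1]; k <- 0L
      for (dr in -3:3) for (dc in -3:3) {
        k <- k + 1L
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) {
          pos <- (rr - 1) * w + c2
          acc <- acc + avg_c[pos] * W7[(k - 1) * 2 + 1, 1] + max_c[pos] * W7[(k - 1) * 2 + 2, 1]
        }
      }
      ms_lin[(r - 1) * w + cc] <- acc
    }
    Ms <- sigm(ms_lin)
    expect_equal(as.vector(out$Ms), Ms, tolerance = 1e-10)
    expect_equal(out$refined, Fc * Ms, tolerance = 1e-10)
    expect_true(all(out$Mc > 0 & out$Mc < 1))
    expect_true(all(out$Ms > 0 & out$Ms < 1))
    expect_true(all(abs(out$refined) <= abs(fmap) + 1e-12))
  }
})

test_that("joint gating follows the concat/split identities and oracle", {
  m <- make_model(27)
  C <- 16L; hw <- 16L
  set.seed(2)
  map_h <- matrix(rnorm(hw * C), hw, C)
  map_c <- matrix(rnorm(hw * C), hw, C)
  # all-zero gate MLP: every gate weight exactly 0.5, channels exactly halved
  mz <- m
  mz$params$spectral$gate$fc1$W[] <- 0; mz$params$spectral$gate$fc1$b[] <- 0
  mz$params$spectral$gate$fc2$W[] <- 0; mz$params$spectral$gate$fc2$b[] <- 0
  out <- joint_gate(mz, map_h, map_c)
  expect_equal(as.vector(out$gate), rep(0.5, 2 * C))
  expect_equal(out$recal_h, map_h / 2)
  # large positive output bias: gates ~ 1, maps pass through within 1e-3
  mb <- m
  mb$params$spectral$gate$fc2$W[] <- 0
  mb$params$spectral$gate$fc2$b[] <- 20
  outb <- joint_gate(mb, map_h, map_c)
  expect_true(all(abs(outb$recal_h - map_h) < 1e-3))
  expect_true(all(abs(outb$recal_c - map_c) < 1e-3))
  # random weights vs explicit hand computation
  p <- m$params$spectral$gate
  gH <- colMeans(map_h); gC <- colMeans(map_c)
  z <- pmax(c(gH, gC) %*% p$fc1$W + as.vector(p$fc1$b), 0) %*% p$fc2$W + as.vector(p$fc2$b)
  gate <- sigm(as.vector(z))
  outr <- joint_gate(m, map_h, map_c)
  expect_equal(as.vector(outr$gate), gate, tolerance = 1e-10)
  expect_equal(outr$recal_c, sweep(map_c, 2, gate[C + seq_len(C)], "*"), tolerance = 1e-10)
  expect_equal(as.vector(outr$fspec),
               c(colMeans(outr$recal_h), colMeans(outr$recal_c)), tolerance = 1e-10)
  # channel-count mismatch is rejected
  expect_error(joint_gate(m, map_h[, 1:8], map_c), "mismatch")
})

test_that("encode_spectra produces a 32-d embedding sensitive to branch order", {
  m <- make_model(28)
  f1 <- rand_img(5); f2 <- rand_img(6)
  fs <- encode_spectra(m, f1, f2)
  expect_equal(dim(fs), c(1L, 32L))
  fs_swapped <- encode_spectra(m, f2, f1)
  expect_gt(max(abs(fs - fs_swapped)), 1e-8)
  # deterministic: same inputs, same parameters, same output
  expect_identical(fs, encode_spectra(m, f1, f2))
})

test_that("full spectral pipeline matches the composed straight-line oracle", {
  m <- make_model(29, multiscale = FALSE) # plain CBAM keeps the oracle tractable
  hw <- ns("backbone_out_hw")(m$backbone)
  f1 <- rand_img(7); f2 <- rand_img(8)
  feats <- extract_backbone_features(m$backbone, f1, f2)
  got <- encode_spectra(m, feats)
  # oracle: reduce -> CBAM (verified against its own oracle above) -> gate
  red <- function(fm, br) {
    p <- m$params$spectral[[br]]$reduce
    sweep(fm %*% p$W, 2, as.vector(p$b), "+")
  }
  bh <- cbam_enhance(m, red(feats$h, "h"), hw, hw, "h")
  bc <- cbam_enhance(m, red(feats$c, "c"), hw, hw, "c")
  jg <- joint_gate(m, bh$refined, bc$refined)
  expect_equal(got, jg$fspec, tolerance = 1e-8)
})
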