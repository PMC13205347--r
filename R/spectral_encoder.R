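# Spectral branch: shared frozen backbone features, per-branch 1x1 channel
# reduction (2048 -> 16), optional parallel 3x3/5x5 multi-scale convolutions,
# branch-specific channel/spatial attention (CBAM), cross-branch joint gating
# and global average pooling into the 32-d spectral embedding f_spec.

init_spectral_encoder <- function(cfg, variant) {
  s <- cfg$spectral
  C <- s$reduced_channels
  r <- s$cbam_ratio
  branch <- function() {
    p <- list(reduce = init_linear(2048L, C, "linear"))
    if (variant$multiscale_spectral) {
      p$ms3 <- init_conv(3L, C, C, "relu")
      p$ms5 <- init_conv(5L, C, C, "relu")
    }
    p$cbam <- list(
      mlp1 = init_linear(C, C %/% r, "relu"),
      mlp2 = init_linear(C %/% r, C, "sigmoid"),
      spatial = init_conv(7L, 2L, 1L, "sigmoid"))
    p
  }
  list(h = branch(), c = branch(),
       gate = list(fc1 = init_linear(2L * C, s$gate_hidden, "relu"),
                   fc2 = init_linear(s$gate_hidden, 2L * C, "sigmoid")))
}

# Channel attention + spatial attention on one branch.
# Fhat: (B*hw) x C node; groups/hw describe image stacking.
cbam_fwd <- function(tape, bp, Fhat, B, h, w) {
  C <- ncol(Fhat$val)
  hw <- h * w
  groups <- rep(seq_len(B), each = hw)
  gap <- ad_group_mean(tape, Fhat, groups)          # B x C
  gmp <- ad_group_max(tape, Fhat, groups)           # B x C
  mlp <- function(x) ly_linear(tape, ad_relu(tape, ly_linear(tape, x, bp$mlp1)), bp$mlp2)
  Mc <- ad_sigmoid(tape, ad_add(tape, mlp(gap), mlp(gmp)))   # B x C in (0,1)
  Fc <- ad_mul(tape, Fhat, ly_expand_rows(tape, Mc, hw))     # channel-refined
  avg_c <- ad_mm(tape, Fc, ad_const(tape, matrix(1 / C, C, 1L)))
  max_c <- ad_rowmax(tape, Fc)
  sp_in <- ad_cbind(tape, list(avg_c, max_c))                # (B*hw) x 2
  Ms <- ad_sigmoid(tape, ly_conv2d(tape, sp_in, bp$spatial, h, w, 7L, B))
  Fb <- ad_mul_colvec(tape, Fc, Ms)
  list(Fb = Fb, Mc = Mc, Ms = Ms)
}

# Full spectral branch forward. feat_h / feat_c: (B*hw) x 2048 constant
# matrices of stacked frozen backbone maps.
spectral_encoder_fwd <- function(tape, pn, feat_h, feat_c, B, h, w, cfg, variant) {
  C <- cfg$spectral$reduced_channels
  hw <- h * w
  groups <- rep(seq_len(B), each = hw)
  one_branch <- function(bp, feats) {
    Fh <- ly_linear(tape, ad_const(tape, feats), bp$reduce) # 1x1 conv == per-pixel linear
    if (variant$multiscale_spectral) {
      Fh <- ad_add(tape, ly_conv2d(tape, Fh, bp$ms3, h, w, 3L, B),
                   ly_conv2d(tape, Fh, bp$ms5, h, w, 5L, B))
    }
    c(list(Fhat = Fh), cbam_fwd(tape, bp$cbam, Fh, B, h, w))
  }
  bh <- one_branch(pn$h, feat_h)
  bc <- one_branch(pn$c, feat_c)
  gH <- ad_group_mean(tape, bh$Fb, groups)  # B x C
  gC <- ad_group_mean(tape, bc$Fb, groups)
  gate <- ad_sigmoid(tape, ly_linear(tape, ad_relu(
    tape, ly_linear(tape, ad_cbind(tape, list(gH, gC)), pn$gate$fc1)), pn$gate$fc2))
  gate_h <- ad_slice_cols(tape, gate, seq_len(C))
  gate_c <- ad_slice_cols(tape, gate, C + seq_len(C))
  recal_h <- ad_mul(tape, bh$Fb, ly_expand_rows(tape, gate_h, hw))
  recal_c <- ad_mul(tape, bc$Fb, ly_expand_rows(tape, gate_c, hw))
  fspec <- ad_cbind(tape, list(ad_group_mean(tape, recal_h, groups),
                               ad_group_mean(tape, recal_c, groups)))
  list(branch_h = bh, branch_c = bc, gate = gate,
       recal_h = recal_h, recal_c = recal_c, fspec = fspec)
}

#' Channel--spatial attention (CBAM) over a reduced feature map
#'
#' Channel weights are the sigmoid of the summed outputs of a shared
#' bottleneck MLP applied to the global-average and global-max descriptors;
#' the channel-refined map is then masked by a spatial attention map computed
#' by a 7x7 convolution over the concatenated channel-wise average and
#' maximum.
#'
#' @param model Model from [build_model()].
#' @param fmap (h*w) x C feature map matrix (row-major spatial order).
#' @param h,w Spatial dimensions.
#' @param branch `"h"` or `"c"`: which branch's parameters to use.
#' @return List with `refined` ((h*w) x C), `Mc` (1 x C channel weights) and
#'   `Ms` ((h*w) x 1 spatial mask), all plain matrices.
#' @export
cbam_enhance <- function(model, fmap, h, w, branch = c("h", "c")) {
  branch <- match.arg(branch)
  tape <- ad_tape()
  out <- cbam_fwd(tape, model$params$spectral[[branch]]$cbam,
                  ad_const(tape, fmap), 1L, h, w)
  list(refined = out$Fb$val, Mc = out$Mc$val, Ms = out$Ms$val)
}

#' Cross-branch joint gating
#'
#' Concatenates the global descriptors of the two attention-refined streams,
#' maps them through the gate MLP and a sigmoid, and splits the resulting
#' weights to rescale the channels of each branch.
#'
#' @param model Model from [build_model()].
#' @param map_h,map_c (h*w) x C refined feature maps.
#' @return List with `gate` (1 x 2C weights in (0,1)), `recal_h`, `recal_c`
#'   (recalibrated maps) and `fspec` (1 x 2C pooled embedding).
#' @export
joint_gate <- function(model, map_h, map_c) {
  if (ncol(map_h) != ncol(map_c)) stop("channel-count mismatch between branches")
  C <- ncol(map_h)
  tape <- ad_tape()
  pn <- model$params$spectral$gate
  gH <- matrix(colMeans(map_h), 1L); gC <- matrix(colMeans(map_c), 1L)
  gate <- ad_sigmoid(tape, ly_linear(tape, ad_relu(
    tape, ly_linear(tape, ad_const(tape, cbind(gH, gC)), pn$fc1)), pn$fc2))
  gv <- as.vector(gate$val)
  recal_h <- sweep(map_h, 2L, gv[seq_len(C)], "*")
  recal_c <- sweep(map_c, 2L, gv[C + seq_len(C)], "*")
  list(gate = gate$val, recal_h = recal_h, recal_c = recal_c,
       fspec = cbind(matrix(colMeans(recal_h), 1L), matrix(colMeans(recal_c), 1L)))
}

#' Encode a pair of spectra into the spectral embedding
#'
#' Orchestrates frozen backbone extraction, 1x1 reduction, per-branch
#' attention, joint gating and global average pooling.
#'
#' @param model Model from [build_model()].
#' @param himg,cimg 256 x 256 x 3 arrays in \[0,1\], or a precomputed feature
#'   list from [extract_backbone_features()] passed as `himg` with `cimg`
#'   missing.
#' @return 1 x (2 * reduced_channels) embedding matrix `f_spec`.
#' @export
encode_spectra <- function(model, himg, cimg) {
  feats <- if (missing(cimg)) himg else extract_backbone_features(model$backbone, himg, cimg)
  hw <- backbone_out_hw(model$backbone)
  tape <- ad_tape()
  out <- spectral_encoder_fwd(tape, model$params$spectral, feats$h, feats$c,
                              1L, hw, hw, model$config, model$variant)
  out$fspec$val
}
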