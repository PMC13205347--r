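# Residual multimodal fusion of the molecule and spectrum embeddings, and
# the sigmoid match classifier.

init_fusion_head <- function(cfg) {
  u_dim <- cfg$graph$embed_dim + 2L * cfg$spectral$reduced_channels
  Fw <- cfg$fusion$width
  Hh <- cfg$head$hidden
  list(
    fusion = list(
      fc1 = init_linear(u_dim, Fw, "relu"),
      bn1 = init_bn(Fw),
      fc2 = init_linear(Fw, Fw, "linear"),
      skip = init_linear(u_dim, Fw, "linear")),
    head = list(
      fc_pred = init_linear(Fw, Hh, "relu"),
      bn = init_bn(Hh),
      # near-zero output layer: logits start symmetric around 0 so the first
      # gradient steps are label-driven rather than correcting random bias
      fc_out = list(W = matrix(stats::rnorm(Hh, sd = 0.01), Hh, 1L),
                    b = matrix(0, 1L, 1L)))
  )
}

# u node (B x u_dim) -> fused node (B x fusion width).
# F_fused = FC2(BN(relu(FC1(u)))) + FC_skip(u)
residual_fuse_fwd <- function(tape, pn, u, bn_state, training) {
  main <- ly_linear(tape, u, pn$fc1)
  main <- ad_batchnorm(tape, ad_relu(tape, main),
                       ad_param_ref(tape, pn$bn1, "gamma"),
                       ad_param_ref(tape, pn$bn1, "beta"),
                       bn_state, training)
  main <- ly_linear(tape, main, pn$fc2)
  ad_add(tape, main, ly_linear(tape, u, pn$skip))
}

# fused node -> logits node (B x 1); y_hat = sigmoid(logits).
head_fwd <- function(tape, pn, fused, bn_state, training) {
  h <- ad_relu(tape, ly_linear(tape, fused, pn$fc_pred))
  h <- ad_batchnorm(tape, h, ad_param_ref(tape, pn$bn, "gamma"),
                    ad_param_ref(tape, pn$bn, "beta"), bn_state, training)
  ly_linear(tape, h, pn$fc_out)
}

#' Residual fusion of molecule and spectrum embeddings
#'
#' The joint representation u = \[f_final; f_spec\] passes through a two-layer
#' main branch (affine, ReLU, batch norm, affine) and is summed with a linear
#' skip projection in the shared output space. Batch normalisation uses the
#' stored running statistics (evaluation mode).
#'
#' @param model Model from [build_model()].
#' @param u Matrix (rows = samples) of joint representations.
#' @return Fused representation matrix (fusion width columns).
#' @export
residual_fuse <- function(model, u) {
  pn <- model$params$fusion
  if (ncol(pn$fc2$W) != ncol(pn$skip$W)) stop("main/skip branch width mismatch")
  tape <- ad_tape()
  residual_fuse_fwd(tape, pn, ad_const(tape, u), model$bn$fusion, training = FALSE)$val
}

#' Match probability from a fused representation
#'
#' @param model Model from [build_model()].
#' @param fused Matrix of fused representations (rows = samples).
#' @return List with `prob` (values strictly in (0,1)) and `label`
#'   (1 when prob >= threshold).
#' @export
predict_match <- function(model, fused) {
  tape <- ad_tape()
  z <- head_fwd(tape, model$params$head, ad_const(tape, fused),
                model$bn$head, training = FALSE)
  p <- 1 / (1 + exp(-z$val))
  list(prob = p, label = as.integer(p >= model$config$head$threshold))
}
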