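# Model assembly, ablation-variant registry, full forward pass and exact
# parameter accounting.

#' Ablation variant registry
#'
#' Five configurations toggling the three architectural components:
#' graph attention (transformer-style), multi-scale graph branches
#' (vs a single GCN stage) and multi-scale spectral attention (vs plain CBAM).
#'
#' @param id One of `"A"`, `"B"`, `"C"`, `"D"`, `"all"`.
#' @return List of logical toggles `attention`, `multiscale_graph`,
#'   `multiscale_spectral`.
#' @export
variant_spec <- function(id) {
  table <- list(
    A   = c(FALSE, FALSE, FALSE),
    B   = c(FALSE, TRUE,  TRUE),
    C   = c(TRUE,  TRUE,  FALSE),
    D   = c(TRUE,  FALSE, TRUE),
    all = c(TRUE,  TRUE,  TRUE))
  if (!id %in% names(table))
    stop("unknown variant '", id, "'; valid ids: ", paste(names(table), collapse = ", "))
  v <- table[[id]]
  list(id = id, attention = v[1], multiscale_graph = v[2], multiscale_spectral = v[3])
}

#' Build a molecule--spectrum matching model
#'
#' Instantiates all trainable parameters for the requested ablation variant
#' plus a frozen spectral backbone. ResNet-101 backbone weights are
#' materialised lazily on first forward pass (parameter accounting does not
#' need them).
#'
#' @param cfg Configuration from [default_config()] (possibly modified).
#' @param variant Variant id (see [variant_spec()]).
#' @param seed Integer seed for parameter initialisation.
#' @return An `nmr_model` object.
#' @export
build_model <- function(cfg = default_config(), variant = "all", seed = 1L) {
  vs <- variant_spec(variant)
  set.seed(seed)
  params <- list(
    graph = init_graph_encoder(cfg, vs),
    spectral = init_spectral_encoder(cfg, vs),
    fusion = NULL, head = NULL)
  fh <- init_fusion_head(cfg)
  params$fusion <- fh$fusion
  params$head <- fh$head
  bn <- list(fusion = bn_state_new(cfg$fusion$width),
             head = bn_state_new(cfg$head$hidden))
  backbone <- new.env(parent = emptyenv())
  backbone$kind <- cfg$spectral$backbone
  backbone$frozen <- TRUE
  backbone$seed <- seed
  backbone$calibration <- NULL
  if (backbone$kind == "tiny") {
    bb <- new_backbone("tiny", seed)
    backbone$weights <- bb$weights
    backbone$calibration <- bb$calibration
  } else backbone$weights <- NULL # materialised lazily
  class(backbone) <- "nmr_backbone"
  model <- structure(list(config = cfg, variant = vs, params = params, bn = bn,
                          backbone = backbone, seed = seed),
                     class = "nmr_model")
  balance_branch_scales(model)
}

# Layer-sequential output-scale initialisation: rescale the last layer of the
# molecule branch and the channel-reduction layer of the spectral branch so
# that both embeddings enter the fusion module at unit per-dimension scale.
# Probes are built in: deterministically sampled molecules for the graph side
# and standard-normal feature maps (the scale the calibrated frozen trunk
# emits) for the spectral side. Purely an initialisation scheme; trained
# parameters move freely afterwards.
balance_branch_scales <- function(model, n_probe = 16L) {
  set.seed(model$seed + 2L)
  cfg <- model$config
  hw <- backbone_out_hw(model$backbone)
  probes <- replicate(n_probe, sample_molecule(c(4L, 16L)), simplify = FALSE)
  bat <- batch_graphs(probes)
  tape <- ad_tape()
  enc <- graph_encoder_fwd(tape, model$params$graph, bat, cfg, model$variant, FALSE)
  s_f <- mean(apply(enc$ffinal$val, 2L, stats::sd))
  if (s_f > 1e-12) {
    model$params$graph$proj2$W <- model$params$graph$proj2$W / s_f
    model$params$graph$proj2$b <- model$params$graph$proj2$b / s_f
  }
  for (it in 1:3) { # reduce feeds sigmoid gates: iterate to a fixed point
    fh <- matrix(stats::rnorm(n_probe * hw * hw * 2048L), n_probe * hw * hw, 2048L)
    fc <- matrix(stats::rnorm(n_probe * hw * hw * 2048L), n_probe * hw * hw, 2048L)
    tape <- ad_tape()
    senc <- spectral_encoder_fwd(tape, model$params$spectral, fh, fc, n_probe,
                                 hw, hw, cfg, model$variant)
    s_s <- mean(apply(senc$fspec$val, 2L, stats::sd))
    if (s_s < 1e-12 || abs(log(s_s)) < 0.05) break
    for (br in c("h", "c")) {
      model$params$spectral[[br]]$reduce$W <- model$params$spectral[[br]]$reduce$W / s_s
      model$params$spectral[[br]]$reduce$b <- model$params$spectral[[br]]$reduce$b / s_s
    }
  }
  model
}

backbone_weights <- function(backbone) {
  if (is.null(backbone$weights))
    backbone$weights <- new_backbone(backbone$kind, backbone$seed)$weights
  backbone$weights
}

#' @export
print.nmr_model <- function(x, ...) {
  pc <- count_parameters(x)
  cat(sprintf("nmr_model (variant %s, backbone %s): %.2f M parameters (%.2f M trainable, %.2f M frozen)\n",
              x$variant$id, x$backbone$kind, pc$total / 1e6,
              pc$trainable / 1e6, pc$frozen / 1e6))
  invisible(x)
}

# ---- forward pass ----

# graphs: list of mol_graph, one per pair; feat_h/feat_c: stacked (B*hw) x 2048
# frozen feature matrices in the same order. Returns nodes + tape.
model_fwd <- function(model, graphs, feat_h, feat_c, training = FALSE,
                      tape = ad_tape(), pnodes = model$params) {
  hw_side <- backbone_out_hw(model$backbone)
  B <- length(graphs)
  bat <- batch_graphs(graphs)
  genc <- graph_encoder_fwd(tape, pnodes$graph, bat, model$config, model$variant, training)
  senc <- spectral_encoder_fwd(tape, pnodes$spectral, feat_h, feat_c, B,
                               hw_side, hw_side, model$config, model$variant)
  u <- ad_cbind(tape, list(genc$ffinal, senc$fspec))
  fused <- residual_fuse_fwd(tape, pnodes$fusion, u, model$bn$fusion, training)
  logits <- head_fwd(tape, pnodes$head, fused, model$bn$head, training)
  list(tape = tape, graph = genc, spectral = senc, u = u, fused = fused,
       logits = logits)
}

#' Predict match probabilities for molecule--spectrum pairs
#'
#' @param model Model from [build_model()].
#' @param graphs List of `mol_graph` objects (candidate molecules).
#' @param feats List of backbone feature pairs (each a list with `h`, `c`
#'   from [extract_backbone_features()]), same length as `graphs`.
#' @return Numeric vector of probabilities in (0,1).
#' @export
predict_pairs <- function(model, graphs, feats) {
  stopifnot(length(graphs) == length(feats))
  fh <- do.call(rbind, lapply(feats, `[[`, "h"))
  fc <- do.call(rbind, lapply(feats, `[[`, "c"))
  out <- model_fwd(model, graphs, fh, fc, training = FALSE)
  as.vector(1 / (1 + exp(-out$logits$val)))
}

# ---- parameter accounting ----

count_mats <- function(x) {
  if (is.list(x)) sum(vapply(x, count_mats, 0)) else length(x)
}

#' Exact parameter counts
#'
#' Integer parameter counts per component and in total, separated into
#' trainable and frozen. The frozen count of the ResNet-101 trunk comes from
#' its architectural definition (materialised weights are not needed).
#'
#' @param model Model from [build_model()].
#' @return List with `total`, `trainable`, `frozen`, `by_component` (named
#'   integer vector) and `total_millions` (rounded to two decimals).
#' @export
count_parameters <- function(model) {
  by_comp <- vapply(model$params, count_mats, 0)
  frozen <- if (model$backbone$kind == "resnet101") resnet101_param_count()
            else count_mats(backbone_weights(model$backbone))
  trainable <- sum(by_comp)
  by_comp <- c(by_comp, backbone = frozen)
  list(total = trainable + frozen, trainable = trainable, frozen = frozen,
       by_component = by_comp,
       total_millions = round((trainable + frozen) / 1e6, 2),
       trainable_millions = round(trainable / 1e6, 2),
       frozen_millions = round(frozen / 1e6, 2))
}

#' Assemble an ablation variant model
#'
#' @param id Variant id (`"A"`, `"B"`, `"C"`, `"D"`, `"all"`).
#' @param cfg Configuration.
#' @param seed Initialisation seed.
#' @return An `nmr_model`.
#' @export
build_variant <- function(id, cfg = default_config(), seed = 1L) {
  build_model(cfg, variant = id, seed = seed)
}
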