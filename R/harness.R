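# Training and evaluation harness: Adam on binary cross-entropy with
# best-validation-accuracy checkpointing, confusion-matrix metrics and
# rank-based AUC.

#' Precompute frozen backbone features for every molecule's spectrum pair
#'
#' The backbone is frozen, so its outputs are computed once per image and
#' cached; training touches only the trainable modules downstream.
#'
#' @param model Model from [build_model()].
#' @param ds Dataset from [generate_dataset()] (rendered images required).
#' @return Named list (by molecule id) of `list(h, c)` feature matrices.
#' @export
prepare_features <- function(model, ds) {
  if (is.null(ds$images)) stop("dataset has no rendered images")
  feats <- vector("list", nrow(ds$molecules))
  names(feats) <- as.character(ds$molecules$id)
  for (i in seq_len(nrow(ds$molecules))) {
    feats[[i]] <- extract_backbone_features(model$backbone,
                                            ds$images[[i]]$h, ds$images[[i]]$c)
  }
  feats
}

# Pre-stack all per-molecule feature maps into two big matrices so that
# batches are single row-gathers.
stack_features <- function(feats) {
  hw <- nrow(feats[[1]]$h)
  list(h = do.call(rbind, lapply(feats, `[[`, "h")),
       c = do.call(rbind, lapply(feats, `[[`, "c")),
       hw = hw, ids = names(feats))
}

stack_batch <- function(ds, fstack, rows) {
  graphs <- ds$graphs[match(rows$mol_id, ds$molecules$id)]
  at <- match(as.character(rows$spec_mol_id), fstack$ids)
  ridx <- as.vector(vapply(at, function(i) (i - 1L) * fstack$hw + seq_len(fstack$hw),
                           integer(fstack$hw)))
  list(graphs = graphs, fh = fstack$h[ridx, , drop = FALSE],
       fc = fstack$c[ridx, , drop = FALSE], y = rows$label)
}

# Deep-copy batch-norm running statistics (stored in environments).
bn_snapshot <- function(bn) lapply(bn, function(st) list(m = st$running_mean, v = st$running_var))
bn_restore <- function(bn, snap) {
  for (k in names(bn)) {
    bn[[k]]$running_mean <- snap[[k]]$m
    bn[[k]]$running_var <- snap[[k]]$v
  }
  invisible(NULL)
}

#' Train a matching model
#'
#' Adam on binary cross-entropy over the `train` split, evaluating accuracy
#' on the `val` split after every epoch and retaining the checkpoint with the
#' highest validation accuracy (earliest epoch wins ties). Only non-frozen
#' parameters are updated; the backbone never changes.
#'
#' @param model Model from [build_model()].
#' @param ds Dataset from [generate_dataset()].
#' @param epochs,batch_size,lr Protocol overrides; defaults come from
#'   `model$config$train` (Adam, lr 1e-4, batch 32).
#' @param seed Seed for batch shuffling and dropout.
#' @param feats Optional precomputed features from [prepare_features()].
#' @param verbose Print per-epoch progress.
#' @return The model with best-checkpoint parameters, plus `log` (per-epoch
#'   loss and validation metrics) and `best_epoch`.
#' @export
train_model <- function(model, ds, epochs = NULL, batch_size = NULL, lr = NULL,
                        seed = 1L, feats = NULL, verbose = FALSE) {
  tc <- model$config$train
  if (is.null(epochs)) epochs <- tc$epochs
  if (is.null(batch_size)) batch_size <- tc$batch_size
  if (is.null(lr)) lr <- tc$lr
  pairs <- model_pairs(ds)
  train_rows <- pairs[pairs$split == "train", ]
  val_rows <- pairs[pairs$split == "val", ]
  if (!nrow(train_rows)) stop("empty train split")
  if (!nrow(val_rows)) stop("empty val split")
  if (is.null(feats)) feats <- prepare_features(model, ds)
  fstack <- stack_features(feats)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  opt <- adam_new(model$params)
  best <- list(acc = -Inf, params = model$params, bn = bn_snapshot(model$bn),
               epoch = 0L)
  log <- data.frame()
  for (ep in seq_len(epochs)) {
    idx <- sample.int(nrow(train_rows))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(idx), by = batch_size)) {
      rows <- train_rows[idx[start:min(start + batch_size - 1L, length(idx))], ]
      b <- stack_batch(ds, fstack, rows)
      tape <- ad_tape()
      pnodes <- ad_params(tape, model$params)
      out <- model_fwd(model, b$graphs, b$fh, b$fc, training = TRUE,
                       tape = tape, pnodes = pnodes)
      lr_ <- ad_bce_sigmoid(tape, out$logits, b$y)
      if (!is.finite(lr_$loss$val[1]))
        stop("non-finite training loss at epoch ", ep, "; check inputs/learning rate")
      ad_backward(tape, lr_$loss)
      upd <- adam_step(model$params, ad_grads(pnodes), opt, lr)
      model$params <- upd$params
      opt <- upd$state
      ep_loss <- ep_loss + lr_$loss$val[1]; nb <- nb + 1L
    }
    vm <- evaluate(model, ds, split = "val", feats = fstack)
    if (vm$Accuracy > best$acc) {
      best <- list(acc = vm$Accuracy, params = model$params,
                   bn = bn_snapshot(model$bn), epoch = ep)
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_accuracy = vm$Accuracy))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f val acc %.3f", ep, ep_loss / nb, vm$Accuracy))
  }
  model$params <- best$params
  bn_restore(model$bn, best$bn)
  model$log <- log
  model$best_epoch <- best$epoch
  model
}

model_pairs <- function(ds) {
  if (inherits(ds, "nmr_dataset")) ds$manifest$pairs else ds$pairs
}

#' Evaluate a model on a manifest split
#'
#' Scores every pair in the split in evaluation mode and computes the
#' confusion matrix at the configured threshold plus Accuracy, Precision,
#' Recall, F1 and rank-based AUC.
#'
#' @param model Trained model.
#' @param ds Dataset.
#' @param split One of `"train"`, `"val"`, `"test_rand"`, `"test_diff"`.
#' @param feats Optional precomputed features.
#' @param batch_size Evaluation batch size.
#' @return A `metrics_report` (see [metrics_report()]), with `scores` and
#'   `labels` attached.
#' @export
evaluate <- function(model, ds, split = "test_rand", feats = NULL,
                     batch_size = 64L) {
  pairs <- model_pairs(ds)
  rows <- pairs[pairs$split == split, ]
  if (!nrow(rows)) stop("split '", split, "' is empty")
  if (is.null(feats)) feats <- prepare_features(model, ds)
  fstack <- if (is.null(feats$ids)) stack_features(feats) else feats
  scores <- numeric(nrow(rows))
  for (start in seq(1L, nrow(rows), by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, nrow(rows))
    b <- stack_batch(ds, fstack, rows[sel, ])
    out <- model_fwd(model, b$graphs, b$fh, b$fc, training = FALSE)
    scores[sel] <- 1 / (1 + exp(-out$logits$val))
  }
  rep <- metrics_report(scores, rows$label, threshold = model$config$head$threshold,
                        split = split)
  rep$scores <- scores
  rep$labels <- rows$label
  rep
}

#' Confusion-matrix metrics and AUC
#'
#' Accuracy is (TP+TN)/(TP+TN+FP+FN); Precision TP/(TP+FP); Recall
#' TP/(TP+FN); F1 their harmonic mean; AUC the Mann-Whitney rank statistic
#' with tie correction. A single-class label vector yields `AUC = NA` with a
#' warning.
#'
#' @param scores Predicted probabilities.
#' @param labels Reference labels in \{0,1\}.
#' @param threshold Decision threshold (default 0.5).
#' @param split Optional split tag carried in the report.
#' @return A `metrics_report` list with TP, TN, FP, FN, Accuracy, Precision,
#'   Recall, F1, AUC, n and split.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5, split = NA_character_) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1L & labels == 1L)
  TN <- sum(pred == 0L & labels == 0L)
  FP <- sum(pred == 1L & labels == 0L)
  FN <- sum(pred == 0L & labels == 1L)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  auc <- if (npos == 0L || nneg == 0L) {
    warning("AUC undefined for a single-class split")
    NA_real_
  } else {
    r <- rank(scores) # average ranks handle ties (tie = 1/2 credit)
    (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  }
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    Accuracy = (TP + TN) / (TP + TN + FP + FN),
    Precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
    Recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    F1 = if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else NA_real_,
    AUC = auc, n = length(labels), split = split), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics [%s] n=%d  TP=%d TN=%d FP=%d FN=%d\n",
              x$split, x$n, x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  Accuracy %.4f  Precision %.4f  Recall %.4f  F1 %.4f  AUC %s\n",
              x$Accuracy, x$Precision, x$Recall, x$F1,
              ifelse(is.na(x$AUC), "NA", sprintf("%.4f", x$AUC))))
  invisible(x)
}

#' Write a metrics report to JSON / CSV
#' @param rep A `metrics_report`.
#' @param path Output file; format by extension (.json or .csv).
#' @export
write_metrics <- function(rep, path) {
  vals <- rep[c("split", "n", "TP", "TN", "FP", "FN", "Accuracy", "Precision",
                "Recall", "F1", "AUC")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(vals), path, row.names = FALSE)
  }
  invisible(path)
}
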