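# Self-Ensemble with Confidence (SEC): weighted soft voting over the
# original test image and its retained augmented copies, using one model.

#' Fuse class-probability vectors by weighted soft voting
#'
#' Accumulates `sum_i w_i * p_i` over the supplied samples and divides by
#' the number of samples; the predicted label is the argmax (ties broken
#' deterministically towards the lowest class index). The fused vector is
#' deliberately not renormalized to sum to one — a normalized copy is
#' provided for display only, since any positive rescaling of the weights
#' leaves the label unchanged.
#'
#' @param probabilities `n_samples x n_classes` matrix, rows summing to 1.
#' @param weights non-negative vector of length `n_samples`, at least one
#'   positive. Zero-weight rows contribute nothing.
#' @return object of class `sec_prediction`: `fused` (accumulated vector),
#'   `fused_normalized`, `label` (0-based class index), `n_contributing`
#'   (rows with positive weight), `weights_used`.
#' @export
sec_fuse <- function(probabilities, weights) {
  if (is.vector(probabilities)) {
    probabilities <- matrix(probabilities, nrow = 1)
  }
  n <- nrow(probabilities)
  if (n < 1 || length(weights) != n) {
    stop_invalid(sprintf("need one weight per probability row (%d rows, %d weights)",
                         n, length(weights)))
  }
  if (any(weights < 0) || any(!is.finite(weights))) {
    stop_invalid("weights must be finite and non-negative")
  }
  if (all(weights == 0)) {
    stop_invalid(paste("all fusion weights are zero; apply the",
                       "original-only fallback before fusing"))
  }
  if (any(abs(rowSums(probabilities) - 1) > 1e-6) || any(probabilities < 0)) {
    stop_invalid("probability rows must be non-negative and sum to 1")
  }
  fused <- as.vector(crossprod(probabilities, weights)) / n
  structure(list(
    fused = fused,
    fused_normalized = fused / sum(fused),
    label = which.max(fused) - 1L,
    n_contributing = sum(weights > 0),
    weights_used = weights
  ), class = "sec_prediction")
}

#' @export
print.sec_prediction <- function(x, ...) {
  cat(sprintf("sec_prediction: label %d (%d contributing samples)\n",
              x$label, x$n_contributing))
  cat("  fused (normalized):",
      paste(sprintf("%.4f", x$fused_normalized), collapse = " "), "\n")
  invisible(x)
}

#' Full filtered test-time-augmentation prediction for one image
#'
#' Composes the pipeline: augment the image, extract multi-layer features
#' for the original and every augmented copy, filter and weight them with
#' the fitted OOD model, then fuse the class probabilities of the retained
#' copies by weighted soft voting. With an empty augmentation set this
#' reduces to the adapter's plain single-image prediction (the Baseline).
#'
#' @param adapter a `classifier_adapter`.
#' @param model a fitted `foods_model`. If it carries an `augmentations`
#'   config it must match `augset`.
#' @param augset an `augmentation_set`; defaults to the model's stored set,
#'   or the empty set if the model stores none.
#' @param image H x W x 3 array in \[0, 1\].
#' @param no_filter retain every augmented copy (weights still computed).
#' @param uniform_weights ignore distance weights (all retained copies
#'   weighted 1).
#' @return a `sec_prediction`; the `filter_decisions` data frame is
#'   attached as attribute `"decisions"`.
#' @export
predict_pipeline <- function(adapter, model, augset = NULL, image,
                             no_filter = FALSE, uniform_weights = FALSE) {
  check_adapter(adapter)
  if (!inherits(model, "foods_model")) {
    stop_invalid("model must be a foods_model")
  }
  if (is.null(augset)) {
    augset <- if (is.null(model$augmentations)) augmentation_set()
              else config_to_augset(model$augmentations)
  }
  if (!is.null(model$augmentations) &&
      !identical(augset_to_config(augset), model$augmentations)) {
    stop_invalid(paste("augmentation set differs from the one stored in",
                       "the fitted model; inference must reuse the",
                       "training-time augmentations"))
  }
  tta <- apply_tta(image, augset)
  feats <- extract_layer_features(adapter, tta)
  decisions <- filter_and_weight(model, feats)
  weights <- decisions$weight
  retained <- decisions$retained
  if (no_filter) {
    retained <- rep(TRUE, length(retained))
    weights <- 1 / pmax(decisions$dbar, model$epsilon)
    weights[!is.finite(weights)] <- 0
    if (weights[1] == 0) weights[1] <- 1
  }
  if (uniform_weights) weights <- as.double(retained)
  keep <- retained & weights > 0
  probs <- batch_probabilities(adapter, tta[keep])
  pred <- sec_fuse(probs, weights[keep])
  attr(pred, "decisions") <- decisions
  pred
}
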