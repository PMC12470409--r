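# Classifier-adapter contract and multi-layer feature extraction.
#
# Any model plugged into the pipeline must expose class probabilities and
# three tagged intermediate feature layers ("low", "mid", "high"); which
# internal activations map to which tag is the adapter's declaration. For
# convolutional feature maps the adapter is expected to pool spatially
# (global average pooling) so each tag yields a fixed-length vector.

check_adapter <- function(adapter) {
  if (!inherits(adapter, "classifier_adapter")) {
    stop_invalid("adapter must be a classifier_adapter")
  }
  adapter
}

#' Extract per-layer feature matrices for a list of images
#'
#' @param adapter a `classifier_adapter`.
#' @param images non-empty list of H x W x 3 arrays.
#' @param tags layer tags to extract; subset of `adapter$layer_tags`.
#' @return named list: one `n_images x d_tag` matrix per tag, rows in input
#'   order, rownames = sample ids (list names, or indices).
#' @export
extract_layer_features <- function(adapter, images,
                                   tags = adapter$layer_tags) {
  check_adapter(adapter)
  if (length(images) == 0) stop_invalid("images must be non-empty")
  if (!all(tags %in% adapter$layer_tags)) {
    stop_invalid("requested tags not declared by the adapter")
  }
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  per_image <- lapply(seq_along(images), function(i) {
    f <- adapter$features(images[[i]])
    for (tag in tags) {
      if (any(!is.finite(f[[tag]]))) {
        stop_data(sprintf(
          "adapter returned non-finite '%s' features for image '%s'",
          tag, ids[i]))
      }
    }
    f
  })
  out <- lapply(tags, function(tag) {
    m <- do.call(rbind, lapply(per_image, function(f) f[[tag]]))
    rownames(m) <- ids
    m
  })
  names(out) <- tags
  out
}

#' Class probabilities for a list of images
#'
#' @param adapter a `classifier_adapter`.
#' @param images non-empty list of images.
#' @return `n_images x n_classes` matrix; every row non-negative and
#'   summing to 1 within 1e-6.
#' @export
batch_probabilities <- function(adapter, images) {
  check_adapter(adapter)
  if (length(images) == 0) stop_invalid("images must be non-empty")
  p <- t(vapply(images, adapter$probabilities, numeric(adapter$n_classes)))
  if (any(!is.finite(p))) stop_data("adapter returned non-finite probabilities")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6)) {
    stop_data("adapter probabilities are not row-stochastic")
  }
  p
}
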