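# Filtering of out-of-distribution samples (FOODS).
#
# Initialisation: for each feature layer, every training sample's average
# Euclidean distance to its k nearest training neighbours (self excluded) is
# computed, and the 95th percentile of those distances becomes the layer's
# threshold tau. At test time an augmented copy is retained only if its
# average k-NN distance is at or below tau on *all* layers; retained copies
# get a fusion weight inversely proportional to their threshold-normalized
# mean distance. Neighbour search is exact (brute force) so results are
# bit-reproducible.

# Pairwise Euclidean distances between rows of `queries` and rows of
# `train`. Accumulates squared differences dimension by dimension rather
# than using the |q|^2 + |t|^2 - 2 q.t expansion: the float sequence is
# then identical to a naive sqrt(sum((q - t)^2)), so exact duplicates give
# exactly zero and results match a brute-force oracle bit for bit.
pairwise_dist <- function(queries, train) {
  d2 <- matrix(0, nrow(queries), nrow(train))
  for (j in seq_len(ncol(train))) {
    d2 <- d2 + outer(queries[, j], train[, j], "-")^2
  }
  sqrt(d2)
}

# Mean of the k smallest values per row of a distance matrix; ties in
# neighbour rank resolved by lowest column (training-row) index, which
# cannot change the mean but fixes *which* rows count as neighbours.
avg_k_smallest <- function(D, k) {
  apply(D, 1, function(d) mean(sort(d, method = "radix")[seq_len(k)]))
}

#' Average distance to the k nearest training samples
#'
#' @param index a `layer_feature_index` (see [fit_foods()]), or any list
#'   with elements `train` (matrix) and `k`.
#' @param query feature vector of length `ncol(index$train)`.
#' @param exclude_self if TRUE the query must equal one of the training
#'   rows; its first matching row is excluded from the neighbour pool.
#' @return mean Euclidean distance to the k nearest training rows.
#' @export
avg_knn_distance <- function(index, query, exclude_self = FALSE) {
  train <- index$train
  k <- index$k
  if (length(query) != ncol(train)) {
    stop_invalid(sprintf("query length %d != feature dimension %d",
                         length(query), ncol(train)))
  }
  d <- pairwise_dist(matrix(query, nrow = 1), train)[1, ]
  if (exclude_self) {
    hit <- which(apply(train, 1, function(r) all(r == query)))
    if (length(hit) == 0) {
      stop_invalid("exclude_self = TRUE but query is not a training row")
    }
    d <- d[-hit[1]]
  }
  if (k > length(d)) {
    stop_invalid(sprintf("k = %d exceeds available neighbours (%d)",
                         k, length(d)))
  }
  mean(sort(d, method = "radix")[seq_len(k)])
}

# Training self-distances for one layer: average distance of every training
# row to its k nearest *other* training rows.
train_self_distances <- function(train, k) {
  D <- pairwise_dist(train, train)
  diag(D) <- Inf
  avg_k_smallest(D, k)
}

#' Fit the out-of-distribution filter
#'
#' @param train_features named list of layer tag -> `n_train x d` feature
#'   matrix (same row order across layers), as returned by
#'   [extract_layer_features()].
#' @param k neighbour count; the default 5 balances robustness and
#'   sensitivity of the local density estimate.
#' @param percentile threshold percentile in (0, 100\]; the default 95
#'   follows standard outlier-detection practice (training samples beyond
#'   the 95th percentile are themselves regarded as outliers). Computed
#'   with linear interpolation between order statistics (R quantile type
#'   7), so ports to other languages can match it exactly.
#' @param epsilon weight floor: fusion weights are `1 / max(dbar, epsilon)`
#'   with `dbar` the mean threshold-normalized distance, so exact
#'   duplicates of training data get the finite maximal weight
#'   `1/epsilon`.
#' @return object of class `foods_model`: per-layer
#'   `layer_feature_index` entries (`tag`, `train`, `k`, `tau`,
#'   `self_distances`) plus `k`, `percentile`, `epsilon`, and an optional
#'   `augmentations` config attached by the caller.
#' @export
fit_foods <- function(train_features, k = 5, percentile = 95,
                      epsilon = 1e-3) {
  if (!is.list(train_features) || is.null(names(train_features)) ||
      any(names(train_features) == "")) {
    stop_invalid("train_features must be a named list of matrices")
  }
  if (percentile <= 0 || percentile > 100) {
    stop_invalid("percentile must be in (0, 100]")
  }
  if (k < 1) stop_invalid("k must be >= 1")
  n <- nrow(train_features[[1]])
  indices <- lapply(names(train_features), function(tag) {
    m <- train_features[[tag]]
    if (!is.matrix(m)) stop_invalid(sprintf("layer '%s' is not a matrix", tag))
    if (nrow(m) != n) stop_invalid("layers disagree on the number of rows")
    if (any(!is.finite(m))) {
      stop_data(sprintf("non-finite features on layer '%s'", tag))
    }
    if (n <= k) {
      stop_data(sprintf("layer '%s': need more than k = %d training rows, got %d",
                        tag, k, n))
    }
    sd <- train_self_distances(m, k)
    tau <- stats::quantile(sd, percentile / 100, type = 7, names = FALSE)
    structure(list(tag = tag, train = m, k = as.integer(k), tau = tau,
                   self_distances = sd),
              class = "layer_feature_index")
  })
  names(indices) <- names(train_features)
  structure(list(indices = indices, k = as.integer(k),
                 percentile = percentile, epsilon = epsilon,
                 augmentations = NULL),
            class = "foods_model")
}

#' @export
print.foods_model <- function(x, ...) {
  cat(sprintf("foods_model: k = %d, percentile = %g, epsilon = %g\n",
              x$k, x$percentile, x$epsilon))
  for (ix in x$indices) {
    cat(sprintf("  layer %-5s n = %d, d = %d, tau = %.6g\n",
                ix$tag, nrow(ix$train), ncol(ix$train), ix$tau))
  }
  invisible(x)
}

# Normalized distance d/tau with the degenerate collapsed-layer convention:
# tau = 0 means only exact duplicates are in-distribution (0 if d == 0,
# +Inf otherwise).
normalize_dist <- function(d, tau) {
  if (tau > 0) return(d / tau)
  ifelse(d == 0, 0, Inf)
}

#' Filter augmented samples and assign fusion weights
#'
#' Row 1 of each feature matrix must be the original test image (M_0); it
#' is never filtered. Augmented rows are retained only if their average
#' k-NN distance is at or below the fitted threshold on every layer;
#' discarded rows get weight 0. Retained rows get weight
#' `1 / max(dbar, epsilon)` where `dbar` is the mean over layers of the
#' threshold-normalized distance.
#'
#' @param model a fitted `foods_model`.
#' @param tta_features named list tag -> feature matrix, row-aligned across
#'   tags, tags matching the fitted model.
#' @return a `filter_decisions` data frame with one row per sample:
#'   `sample_index` (0-based; 0 = original), per-layer raw distances
#'   (`dist_<tag>`), normalized distances (`ndist_<tag>`), `dbar`,
#'   `retained`, `weight`.
#' @export
filter_and_weight <- function(model, tta_features) {
  if (!inherits(model, "foods_model")) {
    stop_invalid("model must be a foods_model")
  }
  tags <- names(model$indices)
  if (!setequal(names(tta_features), tags)) {
    stop_invalid(sprintf("feature tags {%s} do not match fitted model {%s}",
                         paste(names(tta_features), collapse = ","),
                         paste(tags, collapse = ",")))
  }
  n <- nrow(tta_features[[tags[1]]])
  if (any(vapply(tta_features, nrow, 0L) != n)) {
    stop_invalid("tta feature layers disagree on the number of rows")
  }
  dist <- sapply(tags, function(tag) {
    ix <- model$indices[[tag]]
    if (ncol(tta_features[[tag]]) != ncol(ix$train)) {
      stop_invalid(sprintf("layer '%s': query dimension mismatch", tag))
    }
    D <- pairwise_dist(tta_features[[tag]], ix$train)
    avg_k_smallest(D, ix$k)
  })
  dist <- matrix(dist, nrow = n, dimnames = list(NULL, tags))
  ndist <- sapply(tags, function(tag) {
    normalize_dist(dist[, tag], model$indices[[tag]]$tau)
  })
  ndist <- matrix(ndist, nrow = n, dimnames = list(NULL, tags))
  within <- rowSums(ndist <= 1) == length(tags)
  retained <- within
  retained[1] <- TRUE                      # the original is never filtered
  dbar <- rowMeans(ndist)
  weight <- ifelse(retained, 1 / pmax(dbar, model$epsilon), 0)
  if (weight[1] == 0) {
    # collapsed-layer degenerate case: the original's dbar is infinite but
    # it must stay in the ensemble with a positive weight
    weight[1] <- if (any(weight > 0)) min(weight[weight > 0]) else 1
  }
  out <- data.frame(sample_index = seq_len(n) - 1L)
  for (tag in tags) out[[paste0("dist_", tag)]] <- dist[, tag]
  for (tag in tags) out[[paste0("ndist_", tag)]] <- ndist[, tag]
  out$dbar <- dbar
  out$retained <- retained
  out$weight <- weight
  attr(out, "tags") <- tags
  class(out) <- c("filter_decisions", "data.frame")
  out
}

#' Long-format table of threshold-normalized distances
#'
#' One record per (sample, layer): the raw material for the
#' distance-distribution boxplots exported by the evaluation harness.
#'
#' @param decisions a `filter_decisions` data frame.
#' @return data frame with columns `sample_index`, `tag`, `normalized`,
#'   `retained`.
#' @export
normalized_distance_table <- function(decisions) {
  if (nrow(decisions) == 0) stop_invalid("decisions must be non-empty")
  tags <- attr(decisions, "tags")
  do.call(rbind, lapply(tags, function(tag) {
    data.frame(sample_index = decisions$sample_index, tag = tag,
               normalized = decisions[[paste0("ndist_", tag)]],
               retained = decisions$retained)
  }))
}

#' Save / load a fitted filter model
#'
#' R-native serialization; the round trip is bit-exact, so thresholds,
#' stored training features and subsequent filter decisions are identical
#' after reload.
#'
#' @param model a `foods_model`.
#' @param path file path.
#' @return `load_foods` returns the `foods_model`.
#' @export
save_foods <- function(model, path) {
  if (!inherits(model, "foods_model")) {
    stop_invalid("model must be a foods_model")
  }
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_foods
#' @export
load_foods <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("no such model file: %s", path))
  model <- readRDS(path)
  if (!inherits(model, "foods_model")) {
    stop_data(sprintf("%s does not contain a foods_model", path))
  }
  model
}
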