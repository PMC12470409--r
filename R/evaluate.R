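# Evaluation machinery: weighted-average classification metrics, the
# cross-domain (source -> target) experiment runner, the eight-row ablation
# grid with Wilcoxon signed-rank tests against baseline inference, and
# normalized-distance exports for boxplot-style inspection of the filter.

#' Weighted-average classification metrics
#'
#' Per-class precision, recall and F1 from the confusion matrix,
#' aggregated with class support as weights to account for class
#' imbalance; all reported as percentages. Classes with an empty
#' denominator (never predicted, or absent from the truth) get metric 0
#' with a warning.
#'
#' @param y_true,y_pred integer class labels in `0..n_classes-1`, equal
#'   length >= 1.
#' @param n_classes number of classes.
#' @return object of class `metrics_report`: `accuracy`, `precision`,
#'   `recall`, `f1` (weighted, in \[0, 100\]) and a `per_class` data frame.
#' @export
weighted_metrics <- function(y_true, y_pred, n_classes) {
  if (length(y_true) == 0 || length(y_true) != length(y_pred)) {
    stop_invalid("y_true and y_pred must have equal positive length")
  }
  if (any(y_true < 0 | y_true >= n_classes) ||
      any(y_pred < 0 | y_pred >= n_classes)) {
    stop_invalid("labels out of range")
  }
  cm <- table(factor(y_true, levels = 0:(n_classes - 1)),
              factor(y_pred, levels = 0:(n_classes - 1)))
  cm <- matrix(as.numeric(cm), n_classes, n_classes)
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  undef <- pred_n == 0 | support == 0
  if (any(undef & support > 0)) {
    warning("precision undefined for classes never predicted; set to 0",
            call. = FALSE)
  }
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / sum(support)
  structure(list(
    accuracy = 100 * sum(tp) / sum(cm),
    precision = 100 * sum(w * precision),
    recall = 100 * sum(w * recall),
    f1 = 100 * sum(w * f1),
    per_class = data.frame(class = 0:(n_classes - 1),
                           precision = 100 * precision,
                           recall = 100 * recall, f1 = 100 * f1,
                           support = support)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("A %.1f  P %.1f  R %.1f  F1 %.1f (weighted, %%)\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Zero differences are dropped (Wilcoxon's original treatment). For n <=
#' 25 remaining pairs the exact conditional null distribution of the
#' positive-rank sum is computed by dynamic programming over the observed
#' (average, possibly tied) ranks; above that, a normal approximation with
#' tie correction and continuity correction is used. Two-sided.
#'
#' @param x,y paired score vectors; differences are `x - y`. `y` may be
#'   omitted if `x` already holds differences.
#' @return list with `statistic` (positive-rank sum W+), `p.value`, `n`
#'   (non-zero pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  if (length(d) < 1) stop_invalid("need at least one pair")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                method = "all differences zero"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of 2*W+ over all 2^n sign assignments
    r2 <- as.integer(round(2 * r))
    probs <- 1
    for (ri in r2) {
      nxt <- c(probs, numeric(ri)) + c(numeric(ri), probs)
      probs <- nxt / 2
    }
    w2 <- as.integer(round(2 * W))
    lower <- sum(probs[seq_len(w2 + 1L)])
    upper <- sum(probs[(w2 + 1L):length(probs)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' The eight ablation variants of filtered test-time augmentation
#'
#' Every combination of {filtering on/off} x {soft, hard voting} x
#' {distance weights, uniform weights}. With filtering off but weighting
#' on, every augmented copy is kept and the distance-derived weights only
#' modulate the vote.
#'
#' @return data frame with columns `method`, `use_foods`, `voting`,
#'   `weights`.
#' @export
ablation_methods <- function() {
  grid <- expand.grid(weights = c("weighted", "uniform"),
                      voting = c("soft", "hard"),
                      use_foods = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  grid$method <- sprintf("tta_%s_%s_%s",
                         ifelse(grid$use_foods, "foods", "nofoods"),
                         grid$voting, grid$weights)
  grid[, c("method", "use_foods", "voting", "weights")]
}

# Label for one inference variant, from quantities cached per test image.
# probs: (|A|+1) x C matrix; decisions: filter_decisions for the same rows.
predict_variant <- function(probs, decisions, epsilon,
                            use_foods, voting, weights) {
  n <- nrow(probs)
  mask <- if (use_foods) decisions$retained else rep(TRUE, n)
  w <- if (weights == "weighted") {
    if (use_foods) {
      decisions$weight
    } else {
      wv <- 1 / pmax(decisions$dbar, epsilon)
      wv[!is.finite(wv)] <- 0
      wv
    }
  } else {
    rep(1, n)
  }
  w <- w * mask
  if (all(w == 0)) w[1] <- 1
  if (voting == "soft") {
    fused <- as.vector(crossprod(probs, w))
    return(which.max(fused) - 1L)
  }
  votes <- numeric(ncol(probs))
  labs <- max.col(probs, ties.method = "first")
  for (i in which(w > 0)) votes[labs[i]] <- votes[labs[i]] + w[i]
  which.max(votes) - 1L
}

#' Run the cross-domain benchmark
#'
#' For every ordered pair of distinct domains, a training set is generated
#' in the source domain, the classifier adapter and the OOD filter are
#' fitted on it, and every requested inference method is evaluated on a
#' test set generated in the target domain. Per-image test-time features,
#' probabilities and filter decisions are computed once and shared across
#' methods, so the ablation variants are evaluated on identical inputs.
#'
#' @param domains named list of at least two [domain_spec()] objects.
#' @param methods character vector of method names: `"baseline"` and/or
#'   rows of [ablation_methods()].
#' @param adapter_factory function(training dataset) -> classifier adapter.
#' @param n_train_per_class,n_test_per_class dataset sizes per class.
#' @param image_size square image side in pixels.
#' @param seed master seed; all dataset seeds are derived from it.
#' @param k,percentile,epsilon OOD-filter parameters (see [fit_foods()]).
#' @param augset augmentation set; defaults to
#'   [build_default_augmentations()].
#' @return object of class `cross_domain_result`: `scores` — long data
#'   frame (source, target, method, metric, value); `decision_log` — long
#'   normalized-distance records (domain = target); `settings`.
#' @export
run_cross_domain <- function(domains,
                             methods = c("baseline",
                                         ablation_methods()$method),
                             adapter_factory = make_toy_adapter,
                             n_train_per_class = 20, n_test_per_class = 10,
                             image_size = 64, seed = 1, k = 5,
                             percentile = 95, epsilon = 1e-3,
                             augset = NULL) {
  if (length(domains) < 2) stop_invalid("need at least two domains")
  if (is.null(names(domains)) || any(names(domains) == "")) {
    names(domains) <- vapply(domains, function(d) d$name, character(1))
  }
  if (is.null(augset)) augset <- build_default_augmentations(image_size)
  registry <- ablation_methods()
  unknown <- setdiff(methods, c("baseline", registry$method))
  if (length(unknown)) {
    stop_invalid(paste("unknown methods:", paste(unknown, collapse = ", ")))
  }
  variant_rows <- registry[registry$method %in% methods, , drop = FALSE]

  test_sets <- lapply(seq_along(domains), function(ti) {
    generate_dataset(n_test_per_class, domains[[ti]], image_size,
                     seed = derive_seed(seed, 100000L + ti))
  })
  score_rows <- list()
  log_rows <- list()
  for (si in seq_along(domains)) {
    train <- generate_dataset(n_train_per_class, domains[[si]], image_size,
                              seed = derive_seed(seed, si))
    # the classifier and the OOD reference distribution are fitted on
    # originals plus their augmented copies: the same augmentation set is
    # (by assumption) part of training, which is what makes augmented test
    # images candidates for being in-distribution
    train_aug <- augment_dataset(train, augset)
    adapter <- adapter_factory(train_aug)
    train_feats <- extract_layer_features(adapter, train_aug$images)
    model <- fit_foods(train_feats, k = k, percentile = percentile,
                       epsilon = epsilon)
    model$augmentations <- augset_to_config(augset)
    for (ti in seq_along(domains)) {
      if (ti == si) next
      test <- test_sets[[ti]]
      preds <- matrix(NA_integer_, length(test$images),
                      length(methods), dimnames = list(NULL, methods))
      for (ii in seq_along(test$images)) {
        tta <- apply_tta(test$images[[ii]], augset)
        feats <- extract_layer_features(adapter, tta)
        probs <- batch_probabilities(adapter, tta)
        decisions <- filter_and_weight(model, feats)
        for (m in methods) {
          preds[ii, m] <- if (m == "baseline") {
            which.max(probs[1, ]) - 1L
          } else {
            row <- registry[registry$method == m, ]
            predict_variant(probs, decisions, epsilon, row$use_foods,
                            row$voting, row$weights)
          }
        }
        nd <- normalized_distance_table(decisions)
        # the log describes the augmented copies; the original (index 0) is
        # never filtered, so including it would blur the kept/discarded
        # strata
        nd <- nd[nd$sample_index > 0, , drop = FALSE]
        nd$source <- names(domains)[si]
        nd$domain <- names(domains)[ti]
        nd$image <- ii
        log_rows[[length(log_rows) + 1L]] <- nd
      }
      for (m in methods) {
        # warnings about never-predicted classes are routine here: severe
        # shift often collapses predictions onto few classes
        mr <- suppressWarnings(weighted_metrics(test$labels, preds[, m],
                                                n_classes = adapter$n_classes))
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          source = names(domains)[si], target = names(domains)[ti],
          method = m,
          metric = c("accuracy", "precision", "recall", "f1"),
          value = c(mr$accuracy, mr$precision, mr$recall, mr$f1))
      }
    }
  }
  structure(list(
    scores = do.call(rbind, score_rows),
    decision_log = do.call(rbind, log_rows),
    settings = list(domains = names(domains), methods = methods,
                    n_train_per_class = n_train_per_class,
                    n_test_per_class = n_test_per_class,
                    image_size = image_size, seed = seed, k = k,
                    percentile = percentile, epsilon = epsilon)
  ), class = "cross_domain_result")
}

#' Ablation grid with paired significance tests
#'
#' One row per inference variant: the mean paired score difference against
#' baseline and the two-sided Wilcoxon signed-rank p-value, pairing scores
#' over all (source, target, metric) combinations.
#'
#' @param scores a `cross_domain_result` or its long `scores` data frame;
#'   must contain `"baseline"` and all eight variants.
#' @return data frame of class `ablation_grid` with columns `method`,
#'   `use_foods`, `voting`, `weights`, `mean_diff`, `p_value`, `n_pairs`.
#' @export
ablation_grid <- function(scores) {
  if (inherits(scores, "cross_domain_result")) scores <- scores$scores
  registry <- ablation_methods()
  missing <- setdiff(c("baseline", registry$method), unique(scores$method))
  if (length(missing)) {
    stop_invalid(paste("score table is missing methods:",
                       paste(missing, collapse = ", ")))
  }
  key <- function(df) paste(df$source, df$target, df$metric, sep = "|")
  base <- scores[scores$method == "baseline", ]
  base_val <- stats::setNames(base$value, key(base))
  cells <- lapply(seq_len(nrow(registry)), function(i) {
    m <- scores[scores$method == registry$method[i], ]
    paired_base <- base_val[key(m)]
    if (any(is.na(paired_base))) {
      stop_invalid("baseline scores do not cover all method settings")
    }
    diffs <- m$value - paired_base
    wt <- wilcoxon_signed_rank(diffs)
    data.frame(registry[i, , drop = FALSE],
               mean_diff = mean(diffs), p_value = wt$p.value,
               n_pairs = length(diffs))
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  class(out) <- c("ablation_grid", "data.frame")
  out
}

#' Summarise threshold-normalized distance distributions
#'
#' Five-number summaries of the normalized test-time distances, stratified
#' by target domain, feature layer and kept/discarded status — the tabular
#' equivalent of grouped boxplots of the filter's behaviour.
#'
#' @param decision_log long records with columns `domain`, `tag`,
#'   `normalized`, `retained` (as produced by [run_cross_domain()]).
#' @param out_dir optional directory; if given, writes `distances.csv`
#'   (raw records) and `distance_summary.csv`.
#' @return list with `records` (the input) and `summary` (five-number
#'   summary per stratum).
#' @export
export_distance_distributions <- function(decision_log, out_dir = NULL) {
  if (is.null(decision_log) || nrow(decision_log) == 0) {
    stop_invalid("decision log is empty")
  }
  finite <- decision_log[is.finite(decision_log$normalized), ]
  groups <- split(finite,
                  list(finite$domain, finite$tag, finite$retained),
                  drop = TRUE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    q <- stats::quantile(g$normalized, c(0, 0.25, 0.5, 0.75, 1),
                         type = 7, names = FALSE)
    data.frame(domain = g$domain[1], tag = g$tag[1],
               retained = g$retained[1], n = nrow(g),
               min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$domain, summary$tag, summary$retained), ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(decision_log, file.path(out_dir, "distances.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "distance_summary.csv"),
                     row.names = FALSE)
  }
  list(records = decision_log, summary = summary)
}
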