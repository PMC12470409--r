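test_that("weighted metrics match a hand-built confusion-matrix oracle", {
  # perfect predictions
  perfect <- weighted_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0), 3)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$f1, 100)
  # hand example: y_true (0,0,1,1,2,2), y_pred (0,1,1,1,2,0)
  # confusion: class0 TP=1 FN=1; class1 TP=2 FP=1; class2 TP=1 FN=1, FP=0
  r <- weighted_metrics(c(0, 0, 1, 1, 2, 2), c(0, 1, 1, 1, 2, 0), 3)
  expect_equal(r$accuracy, 100 * 4 / 6)
  prec <- c(1 / 2, 2 / 3, 1)       # per class: TP / predicted
  rec <- c(1 / 2, 1, 1 / 2)        # per class: TP / support
  f1 <- 2 * prec * rec / (prec + rec)
  expect_equal(r$per_class$precision, 100 * prec)
  expect_equal(r$per_class$recall, 100 * rec)
  expect_equal(r$precision, 100 * mean(prec))  # equal support -> plain mean
  expect_equal(r$recall, 100 * mean(rec))
  expect_equal(r$f1, 100 * mean(f1))
  # weighted aggregate == support-weighted mean of per-class values
  set.seed(41)
  yt <- sample(0:3, 200, replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
  yp <- ifelse(runif(200) < 0.6, yt, sample(0:3, 200, replace = TRUE))
  m <- suppressWarnings(weighted_metrics(yt, yp, 4))
  w <- m$per_class$support / sum(m$per_class$support)
  expect_equal(m$precision, sum(w * m$per_class$precision), tolerance = 1e-9)
  expect_equal(m$f1, sum(w * m$per_class$f1), tolerance = 1e-9)
})

test_that("degenerate classes yield zero metrics and a warning", {
  expect_warning(r <- weighted_metrics(c(0, 0, 1), c(0, 0, 0), 2),
                 "never predicted")
  expect_equal(r$per_class$precision[2], 0)
  expect_equal(r$per_class$recall[2], 0)
  expect_error(weighted_metrics(integer(0), integer(0), 2),
               class = "ttafilter_invalid_argument")
  expect_error(weighted_metrics(c(0, 5), c(0, 1), 2),
               class = "ttafilter_invalid_argument")
})

test_that("signed-rank test matches exhaustive enumeration for n <= 10", {
  set.seed(51)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    d <- round(stats::rnorm(n), 2)
    if (trial %% 4 == 0) d[sample(n, 2)] <- 0       # zeros dropped
    if (trial %% 3 == 0) d[2] <- d[1]               # ties in |d|
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p.value, oracle_wilcoxon_p(d), tolerance = 1e-12,
                 label = paste("trial", trial))
  }
  # agreement with stats::wilcox.test where its exact path applies
  x <- c(1.1, 2.3, -0.4, 0.8, 1.9, -2.2, 0.3, 1.4)
  ref <- stats::wilcox.test(x, exact = TRUE)
  expect_equal(wilcoxon_signed_rank(x)$p.value, ref$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank handles all-zero differences and shifts", {
  z <- wilcoxon_signed_rank(rep(0, 6))
  expect_equal(z$p.value, 1)
  expect_identical(z$n, 0L)
  # baseline (1..5) vs method (2..6): mean diff 1, all positive signs
  d <- (2:6) - (1:5)
  got <- wilcoxon_signed_rank(2:6, 1:5)
  expect_equal(mean(d), 1)
  expect_equal(got$p.value, oracle_wilcoxon_p(d), tolerance = 1e-12)
  expect_equal(got$p.value, 2 * (1 / 2)^5)  # most extreme assignment
  # large-n normal approximation stays close to the exact oracle at n = 10
  set.seed(52)
  d10 <- rnorm(10) + 0.5
  approx_p <- local({
    r <- rank(abs(d10)); W <- sum(r[d10 > 0]); n <- 10
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    2 * stats::pnorm(-abs((W - mu - 0.5 * sign(W - mu)) / sig))
  })
  expect_equal(wilcoxon_signed_rank(d10)$p.value, oracle_wilcoxon_p(d10),
               tolerance = 1e-12)
  expect_lt(abs(approx_p - oracle_wilcoxon_p(d10)), 0.02)
})

test_that("cross-domain runner enumerates ordered pairs deterministically", {
  doms <- builtin_domains()[c("lab_a", "lab_b")]
  res <- run_cross_domain(doms, methods = "baseline", n_train_per_class = 6,
                          n_test_per_class = 2, seed = 3)
  pairs <- unique(res$scores[, c("source", "target")])
  expect_identical(nrow(pairs), 2L)  # 2 domains -> 2 ordered pairs
  expect_true(all(pairs$source != pairs$target))
  # rerun with the same seed -> identical table
  res2 <- run_cross_domain(doms, methods = "baseline", n_train_per_class = 6,
                           n_test_per_class = 2, seed = 3)
  expect_identical(res2$scores, res$scores)
  expect_error(run_cross_domain(doms[1], methods = "baseline"),
               class = "ttafilter_invalid_argument")
  expect_error(run_cross_domain(doms, methods = "not_a_method"),
               class = "ttafilter_invalid_argument")
})

test_that("ablation grid has 8 cells and honours its reduction properties", {
  # synthetic score table: craft values per method so the grid is checked
  # without a costly benchmark run
  methods <- c("baseline", ablation_methods()$method)
  settings <- expand.grid(source = c("a", "b"), target = c("x", "y"),
                          metric = c("accuracy", "f1"),
                          stringsAsFactors = FALSE)
  set.seed(61)
  rows <- do.call(rbind, lapply(methods, function(m) {
    offset <- if (m == "baseline") 0 else
      which(ablation_methods()$method == m) / 2
    data.frame(settings, method = m,
               value = 70 + offset + rnorm(nrow(settings), sd = 0.1))
  }))
  grid <- ablation_grid(rows)
  expect_s3_class(grid, "ablation_grid")
  expect_identical(nrow(grid), 8L)
  expect_identical(sort(grid$method), sort(ablation_methods()$method))
  expect_true(all(grid$n_pairs == nrow(settings)))
  # method identical to baseline -> mean_diff 0, no significance claimed
  dup <- rows
  dup$value[dup$method == "tta_foods_soft_weighted"] <-
    dup$value[dup$method == "baseline"]
  g2 <- ablation_grid(dup)
  cell <- g2[g2$method == "tta_foods_soft_weighted", ]
  expect_equal(cell$mean_diff, 0)
  expect_equal(cell$p_value, 1)
  # missing variant is an error
  expect_error(ablation_grid(rows[rows$method != "tta_foods_hard_uniform", ]),
               class = "ttafilter_invalid_argument")
})

test_that("distance export summarises strata against an order-statistics oracle", {
  set.seed(71)
  log <- data.frame(
    domain = rep(c("t1", "t2"), each = 60),
    tag = rep(c("low", "mid", "high"), 40),
    sample_index = rep(1:10, 12),
    normalized = c(runif(60, 0, 1), runif(60, 0.5, 3)),
    retained = rep(c(TRUE, FALSE), each = 60)
  )
  out <- export_distance_distributions(log)
  for (i in seq_len(nrow(out$summary))) {
    s <- out$summary[i, ]
    vals <- log$normalized[log$domain == s$domain & log$tag == s$tag &
                           log$retained == s$retained]
    q <- stats::quantile(vals, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")],
                        use.names = FALSE), q, tolerance = 1e-12)
    expect_identical(s$n, length(vals))
  }
  expect_error(export_distance_distributions(log[0, ]),
               class = "ttafilter_invalid_argument")
  # files are written when a directory is given
  d <- tempfile()
  export_distance_distributions(log, out_dir = d)
  expect_true(file.exists(file.path(d, "distances.csv")))
  expect_true(file.exists(file.path(d, "distance_summary.csv")))
})
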