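make_layers <- function(n, dims = c(low = 6, mid = 4, high = 3), seed = 1,
                        shift = 0) {
  ttafilter:::with_seed(seed, {
    out <- lapply(dims, function(d) {
      matrix(stats::rnorm(n * d, mean = shift), n, d)
    })
    names(out) <- names(dims)
    out
  })
}

test_that("average k-NN distance matches hand and brute-force oracles", {
  # hand example: 1-D training set {0..5}, query 10, k = 5 -> mean 35/5 = 7
  index <- list(train = matrix(0:5, ncol = 1), k = 5L)
  expect_equal(avg_knn_distance(index, 10), 7.0)
  # duplicated training rows at the query, self excluded -> distance 0
  dup <- list(train = matrix(rep(c(1, 2), each = 7), ncol = 1), k = 5L)
  expect_equal(avg_knn_distance(dup, 1, exclude_self = TRUE), 0)
  # exhaustive oracle on random instances
  set.seed(42)
  for (rep in 1:5) {
    train <- matrix(rnorm(50 * 8), 50, 8)
    q <- rnorm(8)
    ix <- list(train = train, k = 5L)
    expect_equal(avg_knn_distance(ix, q), oracle_avg_knn(train, q, 5))
    expect_equal(avg_knn_distance(ix, train[17, ], exclude_self = TRUE),
                 oracle_avg_knn(train, train[17, ], 5, exclude_idx = 17))
  }
  expect_error(avg_knn_distance(list(train = matrix(0:3, ncol = 1), k = 5L), 1),
               class = "ttafilter_invalid_argument")
  expect_error(avg_knn_distance(index, c(1, 2)),
               class = "ttafilter_invalid_argument")
})

test_that("fitting computes percentile thresholds with the stated semantics", {
  # identical training rows -> tau = 0 on every layer
  same <- list(low = matrix(1, 10, 3), mid = matrix(2, 10, 2),
               high = matrix(0, 10, 4))
  m0 <- fit_foods(same, k = 5)
  for (ix in m0$indices) expect_equal(ix$tau, 0)
  # percentile semantics on Gaussian features: >= 95% of rows within tau,
  # and the OOD fraction respects the percentile bound per layer
  fe <- make_layers(400, seed = 9)
  m <- fit_foods(fe, k = 5, percentile = 95)
  for (ix in m$indices) {
    frac_in <- mean(ix$self_distances <= ix$tau)
    expect_gte(frac_in, 0.95)
    expect_lte(1 - frac_in, 1 - 0.95 + 1 / 400)
  }
  # percentile = 100 -> no training row beyond tau
  m100 <- fit_foods(fe, k = 5, percentile = 100)
  for (ix in m100$indices) expect_true(all(ix$self_distances <= ix$tau))
  # errors
  expect_error(fit_foods(make_layers(5), k = 5), class = "ttafilter_data_error")
  bad <- make_layers(20); bad$low[3, 1] <- NA
  expect_error(fit_foods(bad), class = "ttafilter_data_error")
})

test_that("retention is the conjunction over layers, verified by brute force", {
  fe <- make_layers(60, seed = 2)
  m <- fit_foods(fe, k = 5)
  set.seed(7)
  for (shift in c(0, 0.5, 1.5)) {
    q <- make_layers(12, seed = 100 + shift * 10, shift = shift)
    dec <- filter_and_weight(m, q)
    want <- oracle_retention(m, q)
    want[1] <- TRUE  # original is never filtered
    expect_identical(dec$retained, want)
    # discarded <=> weight 0; retained <=> weight > 0
    expect_identical(dec$weight > 0, dec$retained)
  }
})

test_that("a row beyond tau on exactly one layer is discarded with weight 0", {
  fe <- make_layers(60, seed = 3)
  m <- fit_foods(fe, k = 5)
  q <- make_layers(2, seed = 4)
  q$high[2, ] <- q$high[2, ] + 100  # push one layer far out
  dec <- filter_and_weight(m, q)
  expect_true(dec$ndist_high[2] > 1)
  expect_false(dec$retained[2])
  expect_identical(dec$weight[2], 0)
})

test_that("weights are inversely proportional to normalized mean distance", {
  # 1-D grid {0..7} with k = 1: every self-distance is 1, so tau = 1 and a
  # query at offset a from a grid point has normalized mean distance a
  fe <- list(low = matrix(c(0, 1, 2, 3, 4, 5, 6, 7), ncol = 1))
  m <- fit_foods(fe, k = 1)
  expect_equal(m$indices$low$tau, 1)
  q <- list(low = matrix(c(0, 2.5, 4.25), ncol = 1))  # dbar 0, 0.5, 0.25
  dec <- filter_and_weight(m, q)
  expect_equal(dec$dbar, c(0, 0.5, 0.25))
  expect_true(all(dec$retained))
  expect_equal(dec$weight[3] / dec$weight[2], 2)  # inverse proportionality
  expect_equal(dec$weight[1], 1 / m$epsilon)      # duplicate -> weight floor
})

test_that("all-duplicate queries collapse to equal maximal weights", {
  # three distinct prototypes, each duplicated 10x: every 5-NN distance is
  # exactly 0, tau = 0, and the degenerate retention path keeps everything
  proto <- make_layers(3, seed = 5)
  fe <- lapply(proto, function(mx) mx[rep(1:3, each = 10), , drop = FALSE])
  q <- proto
  m <- fit_foods(fe, k = 5)
  for (ix in m$indices) expect_equal(ix$tau, 0)
  dec <- filter_and_weight(m, q)
  expect_true(all(dec$retained))
  expect_true(all(dec$weight == 1 / m$epsilon))
  # SEC then reduces to uniform soft voting
  p <- random_prob_matrix(3, 4)
  expect_equal(sec_fuse(p, dec$weight)$fused_normalized,
               colMeans(p) / sum(colMeans(p)), tolerance = 1e-12)
})

test_that("weights are invariant to layer order and monotone in distance", {
  fe <- make_layers(40, seed = 6)
  m <- fit_foods(fe, k = 5)
  q <- make_layers(8, seed = 7)
  dec <- filter_and_weight(m, q)
  # permuted layer order
  perm <- c("high", "low", "mid")
  m2 <- m; m2$indices <- m$indices[perm]
  dec2 <- filter_and_weight(m2, q[perm])
  expect_equal(dec2$weight, dec$weight, tolerance = 1e-12)
  expect_identical(dec2$retained, dec$retained)
  # pushing a retained row further out on one layer cannot raise its weight
  ret <- which(dec$retained & dec$sample_index > 0)
  if (length(ret) > 0) {
    i <- ret[1]
    for (eps in c(0.01, 0.05, 0.1)) {
      q2 <- q
      q2$mid[i, ] <- q$mid[i, ] + eps
      d2 <- filter_and_weight(m, q2)
      expect_lte(d2$weight[i], dec$weight[i] + 1e-12)
    }
  }
})

test_that("normalized distance table restates the retention rule", {
  fe <- make_layers(50, seed = 8)
  m <- fit_foods(fe, k = 5)
  q <- make_layers(10, seed = 9, shift = 0.8)
  dec <- filter_and_weight(m, q)
  tab <- normalized_distance_table(dec)
  expect_identical(nrow(tab), nrow(dec) * 3L)
  aug <- tab[tab$sample_index > 0, ]
  kept <- aug[aug$retained, ]
  if (nrow(kept) > 0) expect_true(all(kept$normalized <= 1))
  disc <- aug[!aug$retained, ]
  if (nrow(disc) > 0) {
    worst <- tapply(disc$normalized, disc$sample_index, max)
    expect_true(all(worst > 1))
  }
})

test_that("serialization round-trips to identical filter decisions", {
  fe <- make_layers(40, seed = 10)
  m <- fit_foods(fe, k = 5)
  path <- tempfile(fileext = ".rds")
  save_foods(m, path)
  m2 <- load_foods(path)
  for (tag in names(m$indices)) {
    expect_identical(m2$indices[[tag]]$tau, m$indices[[tag]]$tau)
  }
  q <- make_layers(6, seed = 11, shift = 0.4)
  expect_identical(filter_and_weight(m2, q), filter_and_weight(m, q))
  expect_error(load_foods(tempfile()), class = "ttafilter_data_error")
})

test_that("tag mismatches are rejected", {
  fe <- make_layers(30, seed = 12)
  m <- fit_foods(fe, k = 5)
  q <- make_layers(3, seed = 13)
  names(q) <- c("low", "mid", "top")
  expect_error(filter_and_weight(m, q), class = "ttafilter_invalid_argument")
})
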