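# Shared fixtures (built in code, memoised per test run) and independent
# oracles used across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small identity-domain dataset + adapter, reused by many tests
tiny_train <- function() {
  memo("tiny_train", generate_dataset(6, identity_domain(), 64, seed = 11))
}
tiny_adapter <- function() {
  memo("tiny_adapter", make_toy_adapter(tiny_train()))
}

# --- independent oracles --------------------------------------------------

# naive loop-and-sort average k-NN distance (exhaustive over all pairs)
oracle_avg_knn <- function(train, query, k, exclude_idx = NULL) {
  d <- apply(train, 1, function(r) sqrt(sum((r - query)^2)))
  if (!is.null(exclude_idx)) d <- d[-exclude_idx]
  mean(sort(d)[seq_len(k)])
}

# exhaustive 2^n sign-assignment Wilcoxon signed-rank p-value (two-sided,
# zeros dropped, average ranks)
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- signs %*% r
  p_low <- mean(ws <= W + 1e-12)
  p_high <- mean(ws >= W - 1e-12)
  min(1, 2 * min(p_low, p_high))
}

# brute-force conjunctive retention rule
oracle_retention <- function(model, tta_features) {
  tags <- names(model$indices)
  n <- nrow(tta_features[[1]])
  sapply(seq_len(n), function(i) {
    ok <- TRUE
    for (tag in tags) {
      ix <- model$indices[[tag]]
      d <- oracle_avg_knn(ix$train, tta_features[[tag]][i, ], ix$k)
      tau <- ix$tau
      ok <- ok && if (tau > 0) d <= tau else d == 0
    }
    ok
  })
}

random_prob_matrix <- function(n, c) {
  m <- matrix(stats::rexp(n * c), n, c)
  m / rowSums(m)
}
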