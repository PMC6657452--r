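# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: literal double loops, exhaustive enumeration,
# grid search, and the covariance-ratio identity for scalability.

# Cliff's delta by literal pair enumeration.
oracle_cliffs_delta <- function(x, y) {
  s <- 0
  for (xi in x) {
    for (yj in y) {
      s <- s + sign(xi - yj)
    }
  }
  s / (length(x) * length(y))
}

# Two-sided rank-sum P by Monte-Carlo permutation of group labels, using
# the rank-sum statistic on midranks and the twice-the-smaller-tail
# convention (the tied null distribution is not symmetric, so the tail
# convention must match the one under test).
oracle_wilcoxon_mc <- function(x, y, n_perm = 10000) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  w_perm <- replicate(n_perm, sum(r[sample(length(r), nx)]))
  min(1, 2 * min(mean(w_perm <= w_obs + 1e-9),
                 mean(w_perm >= w_obs - 1e-9)))
}

# MLE oracle: exhaustive grid search of the joint PCM log-likelihood.
oracle_grid_theta <- function(responses, bounds = c(-4, 4), step = 1e-4) {
  grid <- seq(bounds[1], bounds[2], by = step)
  ll <- numeric(length(grid))
  for (r in responses) {
    k <- 0:length(r$item$thresholds)
    B <- c(0, cumsum(r$item$thresholds))
    L <- outer(grid, k) - rep(B, each = length(grid))
    mx <- do.call(pmax, as.data.frame(L))
    ll <- ll + L[, r$category + 1] - (mx + log(rowSums(exp(L - mx))))
  }
  grid[which.max(ll)]
}

# Exact rank-sum P by full enumeration of group assignments (twice the
# smaller tail, capped at 1).
oracle_wilcoxon_enum <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  sets <- utils::combn(length(pooled), nx)
  w_all <- colSums(matrix(r[sets], nrow = nx))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9),
                 mean(w_all >= w_obs - 1e-9)))
}

# Scalability oracle: H_ij = cov(Xi, Xj) / covmax, covmax being the
# covariance of the comonotonically sorted margins.
oracle_pair_h <- function(x, y) {
  stats::cov(x, y) / stats::cov(sort(x), sort(y))
}

# Random small response sets for MLE checks (excludes all-extreme
# patterns, whose MLE is a bound by construction).
random_response_set <- function(n_items = 5) {
  repeat {
    resp <- lapply(seq_len(n_items), function(i) {
      m <- sample(1:4, 1)
      list(item = pcm_item(paste0("i", i), "d", sort(runif(m, -2, 2))),
           category = sample(0:m, 1))
    })
    score <- sum(vapply(resp, function(r) r$category, numeric(1)))
    maxs <- sum(vapply(resp, function(r) length(r$item$thresholds),
                       numeric(1)))
    if (score > 0 && score < maxs) return(resp)
  }
}

# Small-study configuration for fast pipeline tests: same condition
# proportions, reduced total.
small_synth_config <- function(n = 360, ...) {
  sizes <- c(fixed_none = 56L, fixed_graphical = 62L,
             fixed_graphical_text = 55L, cat_none = 56L,
             cat_graphical = 53L, cat_graphical_text = 65L)
  synth_config(n_respondents = n, condition_sizes = sizes, ...)
}
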