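test_that("Cliff's delta matches exhaustive pair enumeration", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(cliffs_delta(c(2, 3), c(0, 1))$delta, 1)
  expect_equal(cliffs_delta(c(1, 1, 2, 3), c(1, 2, 2, 2))$delta,
               oracle_cliffs_delta(c(1, 1, 2, 3), c(1, 2, 2, 2)))

  set.seed(41)
  for (i in 1:200) {
    x <- sample(0:4, sample(2:30, 1), replace = TRUE)
    y <- sample(0:4, sample(2:30, 1), replace = TRUE)
    res <- cliffs_delta(x, y)
    expect_equal(res$delta, oracle_cliffs_delta(x, y), tolerance = 1e-12)
    expect_equal(res$delta, -cliffs_delta(y, x)$delta)
    expect_lte(abs(res$delta), 1)
    expect_true(res$ci_low <= res$delta && res$delta <= res$ci_high)
    expect_gte(res$ci_low, -1)
    expect_lte(res$ci_high, 1)
  }
  expect_error(cliffs_delta(numeric(0), 1), "non-empty")
})

test_that("delta confidence intervals use the consistent variance estimate", {
  # large-sample check: CI half-width shrinks like 1/sqrt(n) and covers
  set.seed(42)
  x <- rbinom(400, 4, 0.6)
  y <- rbinom(400, 4, 0.5)
  res <- cliffs_delta(x, y)
  expect_lt(res$ci_high - res$ci_low, 0.25)
  # degenerate complete dominance: interval pinned at the boundary
  res2 <- cliffs_delta(c(5, 6), c(1, 2))
  expect_equal(res2$ci_high, 1)
})

test_that("rank-sum P values: exact branch reproduces enumeration results", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6), 0.1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 3), c(2, 2, 3)), 1)
  expect_warning(p <- wilcoxon_rank_sum(rep(2, 5), rep(2, 25)), "identical")
  expect_equal(p, 1)

  # untied small samples: agree with the exact distribution in wilcox.test
  set.seed(43)
  for (i in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    z <- sample(seq_len(100), nx + ny)  # distinct values, no ties
    x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # tied small samples: agree with Monte-Carlo permutation within 3 SE
  set.seed(44)
  for (i in 1:10) {
    x <- sample(0:3, 5, replace = TRUE)
    y <- sample(0:4, 6, replace = TRUE)
    p <- wilcoxon_rank_sum(x, y)
    pmc <- oracle_wilcoxon_mc(x, y)
    # the doubled tail doubles the Monte-Carlo standard error
    q <- pmc / 2
    expect_lt(abs(p - pmc), 6 * sqrt(q * (1 - q) / 10000) + 1e-9)
  }
})

test_that("rank-sum P values: tie-corrected approximation is calibrated", {
  set.seed(45)
  x <- rbinom(120, 4, 0.62)
  y <- rbinom(150, 4, 0.5)
  p <- wilcoxon_rank_sum(x, y)
  # independent route: R's tie-corrected normal approximation
  expect_equal(p, stats::wilcox.test(x, y, exact = FALSE,
                                     correct = TRUE)$p.value,
               tolerance = 1e-9)
  pmc <- oracle_wilcoxon_mc(x, y)
  expect_lt(abs(p - pmc), 6 * sqrt(max(pmc / 2, 1e-4) / 10000) + 0.002)
})

test_that("P values are classified by the .005/.05 convention", {
  expect_equal(classify_p(0.001), "significant")
  expect_equal(classify_p(0.006), "suggestive")
  expect_equal(classify_p(0.05), "null")
  expect_equal(classify_p(0.0049999), "significant")
  expect_error(classify_p(1.2), "\\[0, 1\\]")
})

test_that("Cronbach's alpha follows the variance decomposition", {
  same <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  expect_equal(cronbach_alpha(same)$alpha, 1)

  # hand arithmetic on a 6 x 4 toy matrix
  m <- rbind(c(2, 3, 2, 4), c(1, 2, 2, 3), c(4, 4, 3, 4),
             c(0, 1, 1, 2), c(3, 3, 4, 4), c(2, 2, 1, 1))
  tot <- rowSums(m)
  var_hand <- function(v) sum((v - sum(v) / length(v))^2) / (length(v) - 1)
  alpha_hand <- 4 / 3 * (1 - sum(apply(m, 2, var_hand)) / var_hand(tot))
  expect_equal(cronbach_alpha(m)$alpha, alpha_hand, tolerance = 1e-12)

  set.seed(46)
  ind <- matrix(rnorm(5000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(ind)$alpha), 0.05)

  shifted <- same
  shifted[, 2] <- shifted[, 2] + 10
  expect_equal(cronbach_alpha(shifted)$alpha, cronbach_alpha(same)$alpha)

  expect_error(cronbach_alpha(matrix(1, 4, 4)), "zero variance")
  expect_error(cronbach_alpha(matrix(1:4, ncol = 1)), ">= 2 items")
})

test_that("Loevinger H: perfect scales, hand case, and independence limit", {
  # double monotone pair without Guttman errors
  perfect <- cbind(a = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4),
                   b = c(0, 1, 1, 2, 2, 3, 3, 4, 4, 4))
  expect_equal(loevinger_h(perfect)$scale_h, 1)

  # dichotomous hand computation: F = #(x=0, y=1) = 1,
  # E = n(x=0) n(y=1) / n = 4 * 5 / 10 = 2, H = 1 - 1/2
  x <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  y <- c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0)
  expect_equal(loevinger_h(cbind(x = x, y = y))$scale_h, 0.5)

  set.seed(47)
  ind <- matrix(sample(0:4, 5000 * 4, replace = TRUE), ncol = 4)
  expect_lt(abs(loevinger_h(ind)$scale_h), 0.05)
})

test_that("Loevinger H agrees with the covariance-ratio identity", {
  # toy 10 x 4 polytomous matrix, checked against cov/covmax per pair
  set.seed(48)
  base <- sample(0:2, 10, replace = TRUE)
  m <- sapply(1:4, function(k) pmin(4, base + sample(0:2, 10, replace = TRUE)))
  colnames(m) <- paste0("q", 1:4)
  res <- loevinger_h(m)
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(res$pair_h[i, j], oracle_pair_h(m[, i], m[, j]),
                   tolerance = 1e-12)
    }
  }
  # scale H as error-sum ratio equals the pooled covariance ratio
  covs <- combn(4, 2, function(ij) stats::cov(m[, ij[1]], m[, ij[2]]))
  cmax <- combn(4, 2, function(ij) stats::cov(sort(m[, ij[1]]),
                                              sort(m[, ij[2]])))
  expect_equal(res$scale_h, sum(covs) / sum(cmax), tolerance = 1e-12)

  # invariant under respondent and item permutations
  perm <- loevinger_h(m[sample(10), c(3, 1, 4, 2)])
  expect_equal(sort(perm$item_h), sort(res$item_h), tolerance = 1e-12)
  expect_equal(perm$scale_h, res$scale_h, tolerance = 1e-12)
})

test_that("AISP partitions unrelated item clusters into separate scales", {
  set.seed(49)
  n <- 600
  t1 <- sample(0:4, n, replace = TRUE)
  t2 <- sample(0:4, n, replace = TRUE)
  noisy <- function(t) pmax(0, pmin(4, t + sample(c(-1, 0, 0, 1), n,
                                                  replace = TRUE)))
  m <- cbind(a1 = noisy(t1), a2 = noisy(t1), b1 = noisy(t2), b2 = noisy(t2))
  res <- loevinger_h(m)
  scales <- res$selected_scales$scales
  expect_length(scales, 2)
  expect_true(all(vapply(scales, function(s) {
    identical(s, c("a1", "a2")) || identical(s, c("b1", "b2"))
  }, logical(1))))
  expect_length(res$selected_scales$unscalable, 0)
})
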