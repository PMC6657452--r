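#' Cliff's delta ordinal effect size with confidence interval
#'
#' The dominance statistic for two independent ordinal samples:
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n_x * n_y)`, computed
#' exactly over all pairs. Ranges over `[-1, 1]`; 0 means neither group
#' tends to produce larger values. The confidence interval uses Cliff's
#' consistent variance estimator with a normal quantile, truncated to
#' `[-1, 1]`.
#'
#' @param x,y Numeric (ordinal) samples, both non-empty.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param p_value Optional two-sided P value to attach (usually from
#'   [wilcoxon_rank_sum()]); the verdict field is derived from it via
#'   [classify_p()].
#' @return An object of class `effect_size`: `delta`, `ci_low`,
#'   `ci_high`, `conf_level`, `n_x`, `n_y`, `p_value`, `verdict`.
#' @examples
#' cliffs_delta(c(2, 3, 3, 4), c(1, 2, 2, 3))
#' @export
cliffs_delta <- function(x, y, conf_level = 0.95, p_value = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  d <- sign(outer(x, y, `-`))       # n_x x n_y dominance matrix
  delta <- mean(d)
  di <- rowMeans(d)
  dj <- colMeans(d)
  # consistent variance estimate (Cliff 1993)
  if (nx > 1L && ny > 1L) {
    s2 <- (ny^2 * sum((di - delta)^2) + nx^2 * sum((dj - delta)^2) -
             sum((d - delta)^2)) / (nx * ny * (nx - 1) * (ny - 1))
    s2 <- max(s2, 0)
  } else {
    s2 <- NA_real_
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.na(s2)) c(NA_real_, NA_real_) else delta + c(-1, 1) * z * sqrt(s2)
  structure(
    list(delta = delta,
         ci_low = max(-1, ci[1]), ci_high = min(1, ci[2]),
         conf_level = conf_level, n_x = nx, n_y = ny,
         p_value = p_value,
         verdict = if (is.na(p_value)) NA_character_ else classify_p(p_value)),
    class = "effect_size"
  )
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cliff's delta = %.3f (%d%% CI %.3f to %.3f), n = %d vs %d\n",
              x$delta, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_x, x$n_y))
  if (!is.na(x$p_value)) {
    cat(sprintf("  Wilcoxon P = %.4g (%s)\n", x$p_value, x$verdict))
  }
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum P value
#'
#' For pooled sample sizes up to `exact_max` (default 20) the exact
#' conditional distribution of the rank-sum statistic is enumerated over
#' all equally likely group assignments of the pooled multiset (midranks,
#' so ties are handled by construction) and the two-sided P is twice the
#' smaller tail, capped at 1. For larger samples the tie-corrected normal
#' approximation with a 0.5 continuity correction is used. Likert-type
#' data are heavily tied, so the tie correction matters.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest pooled size for which the exact branch is
#'   used.
#' @return Two-sided P value in `[0, 1]`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(x, y)
  n <- nx + ny
  if (length(unique(pooled)) == 1L) {
    warning("all pooled values identical; P = 1")
    return(1)
  }
  r <- rank(pooled)                 # midranks
  w_obs <- sum(r[seq_len(nx)])
  if (n <= exact_max) {
    # enumerate all C(n, nx) equally likely assignments of ranks to group x
    sets <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[sets], nrow = nx))
    eps <- 1e-9
    p_lo <- mean(w_all <= w_obs + eps)
    p_hi <- mean(w_all >= w_obs - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    warning("degenerate rank variance; P = 1")
    return(1)
  }
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Classify a P value under the reproducibility-oriented convention
#'
#' `P < .005` is called significant; `.005 <= P < .05` suggestive
#' (evidence worth noting but below the stringent threshold); anything
#' else null. Boundaries are strict, so `P = .05` is null.
#'
#' @param p P value in `[0, 1]`.
#' @return One of `"significant"`, `"suggestive"`, `"null"`.
#' @export
classify_p <- function(p) {
  if (!is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("'p' must be in [0, 1]", call. = FALSE)
  }
  if (p < 0.005) "significant" else if (p < 0.05) "suggestive" else "null"
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)` with sample variances
#' (denominator `n - 1`), `k` items, totals summed across items.
#'
#' @param data Numeric matrix or data frame, respondents in rows, items
#'   in columns; at least 2 items and 2 respondents, no missing values.
#' @return An object of class `reliability_result`: `alpha`, `n_items`,
#'   `n_respondents`.
#' @export
cronbach_alpha <- function(data) {
  m <- as.matrix(data)
  if (ncol(m) < 2L || nrow(m) < 2L) {
    stop("need >= 2 items and >= 2 respondents", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  vt <- stats::var(rowSums(m))
  if (vt == 0) stop("total score has zero variance; alpha undefined",
                    call. = FALSE)
  k <- ncol(m)
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / vt)
  structure(list(alpha = alpha, n_items = k, n_respondents = nrow(m)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d respondents)\n",
              x$alpha, x$n_items, x$n_respondents))
  invisible(x)
}

# ---- Mokken scalability ----------------------------------------------------

# Ordered item steps for a polytomous item matrix: one row per step
# (item index, category threshold, popularity = P(X >= c)), sorted by
# decreasing popularity; ties broken by item order then category so the
# ordering is deterministic.
item_steps <- function(m) {
  steps <- do.call(rbind, lapply(seq_len(ncol(m)), function(i) {
    mi <- max(m[, i])
    if (mi < 1) return(NULL)
    data.frame(item = i, cat = seq_len(mi),
               pop = vapply(seq_len(mi), function(c) mean(m[, i] >= c),
                            numeric(1)))
  }))
  steps[order(-steps$pop, steps$item, steps$cat), , drop = FALSE]
}

# Guttman-error weight table for an item pair: weight of cell (a, b) is
# the number of step pairs (s before t in popularity order) with step s
# failed and step t passed -- the polytomous generalization of a Guttman
# error. Within-item step pairs can never contribute because popularity
# within an item is monotone in the category.
pair_weights <- function(steps, i, j, max_i, max_j) {
  sub <- steps[steps$item %in% c(i, j), , drop = FALSE]
  w <- matrix(0, max_i + 1L, max_j + 1L)
  for (a in 0:max_i) {
    for (b in 0:max_j) {
      z <- ifelse(sub$item == i, a >= sub$cat, b >= sub$cat)
      # pairs (s < t) with z_s = 0 and z_t = 1
      w[a + 1L, b + 1L] <- sum(cumsum(!z)[z])
    }
  }
  w
}

# Observed (F) and expected-under-independence (E) weighted Guttman
# errors for one item pair.
pair_errors <- function(m, steps, i, j) {
  max_i <- max(m[, i]); max_j <- max(m[, j])
  w <- pair_weights(steps, i, j, max_i, max_j)
  obs <- table(factor(m[, i], levels = 0:max_i),
               factor(m[, j], levels = 0:max_j))
  n <- nrow(m)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  list(f = sum(obs * w), e = sum(expd * w))
}

#' Mokken scalability analysis (Loevinger's H)
#'
#' Computes item-pair, item and scale scalability coefficients for
#' polytomous items: `H = 1 - F/E`, where `F` is the observed count of
#' category-weighted Guttman errors and `E` its expectation under
#' independence given the marginals. Item and scale coefficients are
#' error-sum ratios (sums of `F` over sums of `E`), not averages of pair
#' coefficients. A scale with `H < .3` is considered weak, `.3 <= H <=
#' .5` medium, and `H > .5` strong. The automated item selection
#' procedure (AISP, greedy variant) partitions the items into scales at
#' a lower bound (default .3).
#'
#' @param data Matrix or data frame of non-negative integer item scores,
#'   respondents in rows; at least 2 items, 3 respondents, no missing
#'   values.
#' @param aisp_lowerbound Lower bound for AISP item admission (default
#'   0.3).
#' @return An object of class `mokken_result`: `item_h` (named vector),
#'   `scale_h`, `pair_h` (matrix), `selected_scales` (list of character
#'   vectors of item names; singleton leftovers collected in
#'   `unscalable`), `classification`.
#' @export
loevinger_h <- function(data, aisp_lowerbound = 0.3) {
  m <- as.matrix(data)
  storage.mode(m) <- "numeric"
  if (ncol(m) < 2L || nrow(m) < 3L) {
    stop("need >= 2 items and >= 3 respondents", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values not allowed", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("item scores must be non-negative integers", call. = FALSE)
  }
  k <- ncol(m)
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("item", seq_len(k))
  steps <- item_steps(m)
  Fm <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  Em <- Fm
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      pe <- pair_errors(m, steps, i, j)
      if (pe$e == 0) {
        warning(sprintf("pair (%s, %s) has zero expected errors; excluded",
                        nm[i], nm[j]))
        next
      }
      Fm[i, j] <- Fm[j, i] <- pe$f
      Em[i, j] <- Em[j, i] <- pe$e
    }
  }
  pair_h <- 1 - Fm / Em
  item_h <- 1 - rowSums(Fm, na.rm = TRUE) / rowSums(Em, na.rm = TRUE)
  names(item_h) <- nm
  tot_e <- sum(Em[upper.tri(Em)], na.rm = TRUE)
  scale_h <- if (tot_e > 0) 1 - sum(Fm[upper.tri(Fm)], na.rm = TRUE) / tot_e
             else NA_real_
  classification <- if (is.na(scale_h)) NA_character_
    else if (scale_h < 0.3) "weak"
    else if (scale_h > 0.5) "strong"
    else "medium"
  structure(
    list(item_h = item_h, scale_h = scale_h, pair_h = pair_h,
         selected_scales = aisp_greedy(Fm, Em, nm, aisp_lowerbound),
         classification = classification),
    class = "mokken_result"
  )
}

# Greedy AISP: seed each scale with the remaining pair of highest pair H
# (if >= lowerbound), then repeatedly add the candidate whose item H
# against the current scale is highest, while it stays >= lowerbound.
aisp_greedy <- function(Fm, Em, nm, lowerbound) {
  k <- length(nm)
  remaining <- seq_len(k)
  scales <- list()
  pair_h <- 1 - Fm / Em
  item_h_vs <- function(c, members) {
    1 - sum(Fm[c, members]) / sum(Em[c, members])
  }
  while (length(remaining) >= 2L) {
    sub <- pair_h[remaining, remaining, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- NA
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) < lowerbound) break
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    scale <- remaining[c(ij[1L], ij[2L])]
    remaining <- setdiff(remaining, scale)
    repeat {
      if (!length(remaining)) break
      h_cand <- vapply(remaining, item_h_vs, numeric(1), members = scale)
      best <- which.max(h_cand)
      if (h_cand[best] < lowerbound) break
      scale <- c(scale, remaining[best])
      remaining <- remaining[-best]
    }
    scales[[length(scales) + 1L]] <- nm[sort(scale)]
  }
  list(scales = scales, unscalable = nm[sort(remaining)])
}

#' @export
print.mokken_result <- function(x, ...) {
  cat(sprintf("Mokken scale analysis: scale H = %.3f (%s)\n",
              x$scale_h, x$classification))
  cat("  item H:\n")
  for (i in seq_along(x$item_h)) {
    cat(sprintf("    %-12s %.3f\n", names(x$item_h)[i], x$item_h[i]))
  }
  ns <- length(x$selected_scales$scales)
  cat(sprintf("  AISP: %d scale%s", ns, if (ns == 1L) "" else "s"))
  if (length(x$selected_scales$unscalable)) {
    cat(sprintf(", unscalable: %s",
                paste(x$selected_scales$unscalable, collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}
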