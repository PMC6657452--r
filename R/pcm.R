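#' Construct a partial credit model item
#'
#' A polytomous Rasch item under Masters' partial credit model (PCM). An
#' item with `m` step thresholds has `m + 1` ordered response categories
#' `0..m`; threshold `b_j` (logit units) is the point on the latent scale
#' at which categories `j - 1` and `j` are equally likely.
#'
#' @param item_id Character scalar identifying the item.
#' @param domain_id Character scalar naming the domain the item measures.
#' @param thresholds Numeric vector of step parameters, length >= 1, all
#'   finite. Need not be ordered (disordered thresholds are admissible in
#'   the PCM).
#' @return An object of class `pcm_item`.
#' @examples
#' it <- pcm_item("phys01", "physical", c(-1, 0, 1, 2))
#' pcm_category_probs(it, theta = 0.5)
#' @export
pcm_item <- function(item_id, domain_id, thresholds) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || !all(is.finite(thresholds))) {
    stop("'thresholds' must be a non-empty vector of finite values",
         call. = FALSE)
  }
  structure(
    list(item_id = as.character(item_id)[1L],
         domain_id = as.character(domain_id)[1L],
         thresholds = unname(thresholds)),
    class = "pcm_item"
  )
}

#' @export
print.pcm_item <- function(x, ...) {
  cat(sprintf("PCM item '%s' (domain %s): %d categories, thresholds %s\n",
              x$item_id, x$domain_id, length(x$thresholds) + 1L,
              paste(format(x$thresholds, digits = 3), collapse = ", ")))
  invisible(x)
}

is_pcm_item <- function(x) inherits(x, "pcm_item")

stop_if_bad_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop("'theta' must be a single finite number", call. = FALSE)
  }
}

#' PCM category response probabilities
#'
#' Probability of each response category `0..m` for a PCM item at a given
#' latent trait value: `P(X = k | theta)` is proportional to
#' `exp(sum_{j<=k}(theta - b_j))`, with an empty sum for `k = 0`.
#' Computed on the log scale with max subtraction, so extreme `theta` are
#' safe.
#'
#' @param item A [pcm_item()].
#' @param theta Latent trait value (logit units), finite scalar.
#' @return Numeric vector of length `m + 1` summing to 1, names `"0"..

#'   "m"`.
#' @export
pcm_category_probs <- function(item, theta) {
  if (!is_pcm_item(item)) stop("'item' must be a pcm_item", call. = FALSE)
  stop_if_bad_theta(theta)
  # log numerators: 0, cumsum(theta - b_j)
  lognum <- c(0, cumsum(theta - item$thresholds))
  lognum <- lognum - max(lognum)
  p <- exp(lognum)
  p <- p / sum(p)
  names(p) <- as.character(seq_along(p) - 1L)
  p
}

#' Fisher information of a PCM item
#'
#' Under the Rasch family the item score is a sufficient statistic and the
#' Fisher information at `theta` equals the conditional variance of the
#' category index, `Var(X | theta)`. Observed and expected information
#' coincide.
#'
#' @inheritParams pcm_category_probs
#' @return Non-negative scalar.
#' @export
pcm_item_information <- function(item, theta) {
  p <- pcm_category_probs(item, theta)
  k <- seq_along(p) - 1
  ex <- sum(k * p)
  sum((k - ex)^2 * p)
}

#' Expected item score under the PCM
#'
#' `E[X | theta]`, strictly increasing in `theta`. Its derivative is the
#' item information.
#'
#' @inheritParams pcm_category_probs
#' @return Scalar in `[0, m]`.
#' @export
pcm_expected_score <- function(item, theta) {
  p <- pcm_category_probs(item, theta)
  sum((seq_along(p) - 1) * p)
}

# Joint PCM log-likelihood of a response set, vectorized over theta.
# lognum_k(theta) = k*theta - B_k with B_k = cumsum(b), B_0 = 0.
pcm_loglik <- function(responses, theta) {
  ll <- numeric(length(theta))
  for (r in responses) {
    k <- 0:length(r$item$thresholds)
    B <- c(0, cumsum(r$item$thresholds))
    L <- outer(theta, k) - rep(B, each = length(theta))
    mx <- apply(L, 1L, max)
    logZ <- mx + log(rowSums(exp(L - mx)))
    ll <- ll + L[, r$category + 1L] - logZ
  }
  ll
}

check_responses <- function(responses) {
  if (length(responses) == 0L) {
    stop("at least one (item, category) response is required", call. = FALSE)
  }
  for (r in responses) {
    if (!is.list(r) || !is_pcm_item(r$item) || is.null(r$category)) {
      stop("each response must be list(item = <pcm_item>, category = <int>)",
           call. = FALSE)
    }
    m <- length(r$item$thresholds)
    x <- r$category
    if (!is.numeric(x) || length(x) != 1L || x != round(x) || x < 0 || x > m) {
      stop(sprintf("category %s out of range 0..%d for item '%s'",
                   format(x), m, r$item$item_id), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Maximum-likelihood trait estimation for PCM responses
#'
#' Maximizes the joint PCM log-likelihood of a set of scored responses
#' over a bounded interval, by 1-D golden-section/parabolic search
#' ([stats::optimize()], tolerance 1e-6). The standard error is
#' `1 / sqrt(sum of item informations at the estimate)`; for the Rasch
#' family observed and expected information coincide, and the likelihood
#' is strictly concave whenever the summed score is not at either extreme.
#'
#' Response patterns with every item at its minimum (or maximum) category
#' have no finite maximizer; the estimate is clamped to the corresponding
#' bound and `converged` is `FALSE`.
#'
#' @param responses List of responses, each `list(item = <pcm_item>,
#'   category = <integer>)`.
#' @param bounds Numeric length-2 interval for the estimate; default
#'   `c(-4, 4)`.
#' @return An object of class `theta_estimate`: a list with `theta`, `se`,
#'   `n_items_used`, `converged`.
#' @examples
#' bank <- list(pcm_item("a", "d", c(-1, 0, 1)), pcm_item("b", "d", 0))
#' resp <- list(list(item = bank[[1]], category = 2),
#'              list(item = bank[[2]], category = 0))
#' estimate_theta_mle(resp)
#' @export
estimate_theta_mle <- function(responses, bounds = c(-4, 4)) {
  check_responses(responses)
  if (!is.numeric(bounds) || length(bounds) != 2L || bounds[1] >= bounds[2]) {
    stop("'bounds' must be an increasing length-2 interval", call. = FALSE)
  }
  score <- sum(vapply(responses, function(r) r$category, numeric(1)))
  max_score <- sum(vapply(responses, function(r) length(r$item$thresholds),
                          numeric(1)))
  if (score == 0 || score == max_score) {
    theta <- if (score == 0) bounds[1] else bounds[2]
    converged <- FALSE
  } else {
    opt <- stats::optimize(function(th) pcm_loglik(responses, th),
                           interval = bounds, maximum = TRUE, tol = 1e-6)
    theta <- opt$maximum
    converged <- TRUE
  }
  info <- sum(vapply(responses,
                     function(r) pcm_item_information(r$item, theta),
                     numeric(1)))
  se <- if (info > 0) 1 / sqrt(info) else Inf
  structure(
    list(theta = theta, se = se, n_items_used = length(responses),
         converged = converged),
    class = "theta_estimate"
  )
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta = %.4f (SE %.4f), %d item%s%s\n",
              x$theta, x$se, x$n_items_used,
              if (x$n_items_used == 1L) "" else "s",
              if (x$converged) "" else " [boundary estimate]"))
  invisible(x)
}
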