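#' Adaptive test configuration
#'
#' Collects the tunable parameters of the adaptive administration loop
#' and of the norm-referenced score transformation.
#'
#' @param se_stop Standard-error stopping threshold (logit units).
#'   Administration stops once the provisional trait estimate's SE drops
#'   below this value. Default 0.45.
#' @param max_items_per_domain Hard cap on items per domain; `Inf` means
#'   the bank is the only limit.
#' @param min_items_per_domain Minimum items before the SE rule is
#'   evaluated (default 2; the SE after a single item is rarely
#'   meaningful and never below typical thresholds).
#' @param theta_init Starting trait value used to select the first item
#'   (default 0, the population mean).
#' @param bounds Estimation interval passed to [estimate_theta_mle()].
#' @param norms Named list mapping `domain_id` to `list(mean, sd)` of the
#'   reference-population trait distribution (logit units), used by
#'   [theta_to_domain_score()]. May be `NULL` if scores are not needed.
#' @return An object of class `cat_config`.
#' @export
cat_config <- function(se_stop = 0.45, max_items_per_domain = Inf,
                       min_items_per_domain = 2L, theta_init = 0,
                       bounds = c(-4, 4), norms = NULL) {
  if (!is.numeric(se_stop) || se_stop <= 0) {
    stop("'se_stop' must be > 0", call. = FALSE)
  }
  if (min_items_per_domain < 1L || max_items_per_domain < min_items_per_domain) {
    stop("need max_items_per_domain >= min_items_per_domain >= 1",
         call. = FALSE)
  }
  if (!is.null(norms)) {
    ok <- vapply(norms, function(nm) {
      is.list(nm) && is.numeric(nm$mean) && is.numeric(nm$sd) && nm$sd > 0
    }, logical(1))
    if (!all(ok)) stop("each norm must be list(mean, sd) with sd > 0",
                       call. = FALSE)
  }
  structure(
    list(se_stop = se_stop,
         max_items_per_domain = max_items_per_domain,
         min_items_per_domain = as.integer(min_items_per_domain),
         theta_init = theta_init, bounds = bounds, norms = norms),
    class = "cat_config"
  )
}

#' Select the next item by maximum Fisher information
#'
#' Scans the unadministered items of the session's domain and returns the
#' one with the largest [pcm_item_information()] at the provisional trait
#' estimate; ties are broken by lexicographic `item_id` so selection is
#' deterministic.
#'
#' @param bank An [item_bank()].
#' @param administered_ids Character vector of item ids already used.
#' @param theta Provisional trait estimate.
#' @param domain_id Domain being assessed.
#' @return A [pcm_item()], or `NULL` if the domain's bank is exhausted.
#' @export
select_next_item <- function(bank, administered_ids, theta, domain_id) {
  cand <- bank_items(bank, domain_id)
  cand <- cand[!names(cand) %in% administered_ids]
  if (!length(cand)) return(NULL)
  info <- vapply(cand, pcm_item_information, numeric(1), theta = theta)
  ids <- names(cand)
  best <- info == max(info)
  cand[[min(which(best & ids == min(ids[best])))]]
}

#' Run one adaptive assessment session for a domain
#'
#' The administration loop: select the most informative unadministered
#' item at the current trait estimate, obtain a response from
#' `responder`, re-estimate theta by maximum likelihood, and repeat until
#' the first of: SE below `config$se_stop` (once at least
#' `min_items_per_domain` items are answered), the domain bank is
#' exhausted, or `max_items_per_domain` is reached.
#'
#' @param bank An [item_bank()].
#' @param responder Function `(pcm_item) -> integer category`; typically a
#'   simulated respondent such as [pcm_responder()], or a closure looking
#'   up recorded answers.
#' @param config A [cat_config()].
#' @param domain_id Domain to assess.
#' @return An object of class `cat_session`: `domain_id`, `administered`
#'   (data.frame item_id/category), `trajectory` (list of
#'   [estimate_theta_mle()] results after each response), `final`
#'   (last trait estimate), `stopped_reason` (one of `"se_reached"`,
#'   `"bank_exhausted"`, `"max_items"`).
#' @export
run_cat <- function(bank, responder, config = cat_config(), domain_id) {
  if (!length(bank_items(bank, domain_id))) {
    stop("bank has no items for domain '", domain_id, "'", call. = FALSE)
  }
  administered <- list()
  trajectory <- list()
  responses <- list()
  theta <- config$theta_init
  stopped_reason <- NULL
  repeat {
    item <- select_next_item(bank, vapply(administered, `[[`, character(1),
                                          "item_id"),
                             theta, domain_id)
    if (is.null(item)) {
      stopped_reason <- "bank_exhausted"
      break
    }
    x <- responder(item)
    m <- length(item$thresholds)
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < 0 || x > m) {
      stop(sprintf("responder returned invalid category %s for item '%s' (range 0..%d)",
                   format(x), item$item_id, m), call. = FALSE)
    }
    administered[[length(administered) + 1L]] <-
      list(item_id = item$item_id, category = as.integer(x))
    responses[[length(responses) + 1L]] <- list(item = item, category = x)
    est <- estimate_theta_mle(responses, bounds = config$bounds)
    trajectory[[length(trajectory) + 1L]] <- est
    theta <- est$theta
    n <- length(responses)
    if (n >= config$min_items_per_domain && est$se < config$se_stop) {
      stopped_reason <- "se_reached"
      break
    }
    if (n >= config$max_items_per_domain) {
      stopped_reason <- "max_items"
      break
    }
  }
  structure(
    list(domain_id = domain_id,
         administered = data.frame(
           item_id = vapply(administered, `[[`, character(1), "item_id"),
           category = vapply(administered, `[[`, integer(1), "category"),
           stringsAsFactors = FALSE),
         trajectory = trajectory,
         final = if (length(trajectory)) trajectory[[length(trajectory)]] else NULL,
         stopped_reason = stopped_reason),
    class = "cat_session"
  )
}

#' @export
print.cat_session <- function(x, ...) {
  n <- nrow(x$administered)
  cat(sprintf("Adaptive session, domain %s: %d item%s, stopped (%s)\n",
              x$domain_id, n, if (n == 1L) "" else "s", x$stopped_reason))
  if (!is.null(x$final)) {
    cat(sprintf("  final theta %.3f (SE %.3f)\n", x$final$theta, x$final$se))
  }
  invisible(x)
}

#' Simulated PCM respondent
#'
#' Returns a responder closure for [run_cat()]: given an item, samples a
#' category from [pcm_category_probs()] at the respondent's true trait
#' value. Uses the current RNG stream.
#'
#' @param theta True latent trait of the simulated respondent.
#' @return Function `(pcm_item) -> integer`.
#' @export
pcm_responder <- function(theta) {
  force(theta)
  function(item) {
    p <- pcm_category_probs(item, theta)
    sample(seq_along(p) - 1L, 1L, prob = p)
  }
}

#' Norm-referenced 0-100 domain score
#'
#' Standardizes a trait estimate against the reference population for its
#' domain (`z = (theta - mean) / sd`) and maps it linearly to the 0-100
#' reporting scale: `50 + (100/6) * z`, clipped to `[0, 100]`, so that
#' +/- 3 reference SDs span the scale. 0 is the worst and 100 the best
#' possible quality of life.
#'
#' @param theta_est A [estimate_theta_mle()] result (or any list with a
#'   `theta` field).
#' @param config A [cat_config()] whose `norms` contain `domain_id`.
#' @param domain_id Domain of the score.
#' @return An object of class `domain_score`: `domain_id`, `z`,
#'   `score_0_100`, `source = "cat"`.
#' @export
theta_to_domain_score <- function(theta_est, config, domain_id) {
  nm <- config$norms[[domain_id]]
  if (is.null(nm)) {
    stop("no norm parameters configured for domain '", domain_id, "'",
         call. = FALSE)
  }
  z <- (theta_est$theta - nm$mean) / nm$sd
  structure(
    list(domain_id = domain_id, z = z,
         score_0_100 = min(100, max(0, 50 + (100 / 6) * z)),
         source = "cat"),
    class = "domain_score"
  )
}

#' @export
print.domain_score <- function(x, ...) {
  cat(sprintf("%s: %.1f / 100 (z = %+.2f, %s)\n",
              x$domain_id, x$score_0_100, x$z, x$source))
  invisible(x)
}
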