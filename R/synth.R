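#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic six-condition experiment: the two
#' assessment forms (fixed-length vs adaptive) crossed with three
#' feedback conditions (none, graphical, graphical plus tailored text).
#' Defaults emulate a crowdsourced general-population sample of 1454
#' respondents whose post-filter condition sizes, acceptability effect
#' sizes, attention-check failure rate and feedback-viewing times match
#' the study conditions the package is designed to analyse.
#'
#' @param n_respondents Total respondents generated (default 1454).
#' @param condition_sizes Named integer vector of target analysis-sample
#'   sizes for the six conditions (defaults 226, 247, 219, 223, 211, 260
#'   for fixed/none, fixed/graphical, fixed/graphical_text, cat/none,
#'   cat/graphical, cat/graphical_text). The generator allocates
#'   `n_respondents` proportionally to these, so that after attention
#'   filtering the expected per-condition sizes equal the targets.
#' @param target_deltas Named list of population Cliff's deltas, each
#'   relative to the fixed/none control, used to calibrate the latent
#'   location shift of the corresponding condition. Recognised names:
#'   the condition names above, plus `pooled_graphical_text` which gives
#'   both graphical_text arms one common shift calibrated so that the
#'   pooled graphical_text vs pooled no-feedback population delta equals
#'   the target. Defaults: fixed_graphical 0.09, cat_none -0.11,
#'   cat_graphical 0.01, pooled_graphical_text 0.22.
#' @param attention_fail_rate Probability a respondent endorses the "I
#'   have not been paying attention" check (default 68/1454).
#' @param time_medians Named vector of median feedback-viewing seconds
#'   for the four feedback conditions (defaults 115, 132, 124, 147).
#' @param time_log_sd Log-scale SD of the log-normal viewing-time
#'   distribution (default 0.6, giving the right-skew typical of viewing
#'   times).
#' @param item_cutpoints 4 x 4 numeric matrix: row `k` holds the ordered
#'   latent cutpoints of acceptability item `k` (categories 0-4).
#'   Defaults are chosen so the control condition reproduces
#'   positively-skewed item means of roughly 3.2, 3.3, 2.1 and 2.9.
#' @param noise_scale Scale of the logistic item-specific noise added to
#'   the respondent's latent acceptability before discretization
#'   (default 0.95; smaller values make the four items more strongly
#'   related -- the default yields Cronbach's alpha near .77 and
#'   Loevinger's H near .53 at the study sample size).
#' @param appraisal_probs Named list of length-5 category probability
#'   vectors for the feedback-appraisal items `graph_accurate`,
#'   `graph_clear`, `text_accurate`, `text_clear`.
#' @param bank_spec List describing generated adaptive item banks:
#'   `domains`, `n_items_per_domain`, `n_steps`, `center_range`,
#'   `step_spread`, `threshold_jitter_sd`. See [generate_bank()]. The
#'   default dispersion is calibrated so that an adaptive run over the
#'   four 25-item domain banks with the 0.45 SE stopping rule
#'   administers about 18 items in total.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(
    n_respondents = 1454L,
    condition_sizes = c(fixed_none = 226L, fixed_graphical = 247L,
                        fixed_graphical_text = 219L, cat_none = 223L,
                        cat_graphical = 211L, cat_graphical_text = 260L),
    target_deltas = list(fixed_graphical = 0.09, cat_none = -0.11,
                         cat_graphical = 0.01,
                         pooled_graphical_text = 0.22),
    attention_fail_rate = 68 / 1454,
    time_medians = c(fixed_graphical = 115, fixed_graphical_text = 132,
                     cat_graphical = 124, cat_graphical_text = 147),
    time_log_sd = 0.6,
    item_cutpoints = default_item_cutpoints(),
    noise_scale = 0.95,
    appraisal_probs = default_appraisal_probs(),
    bank_spec = list(domains = c("physical", "psychological", "social",
                                 "environment"),
                     n_items_per_domain = 25L, n_steps = 4L,
                     center_range = c(-2, 2), step_spread = 0.25,
                     threshold_jitter_sd = 0.15)) {
  conds <- c("fixed_none", "fixed_graphical", "fixed_graphical_text",
             "cat_none", "cat_graphical", "cat_graphical_text")
  if (!identical(sort(names(condition_sizes)), sort(conds))) {
    stop("'condition_sizes' must be named by the six conditions",
         call. = FALSE)
  }
  if (sum(condition_sizes) > n_respondents) {
    stop("condition sizes must sum to at most n_respondents", call. = FALSE)
  }
  if (attention_fail_rate < 0 || attention_fail_rate > 1) {
    stop("'attention_fail_rate' must be in [0, 1]", call. = FALSE)
  }
  bad <- vapply(target_deltas, function(d) abs(d) >= 1, logical(1))
  if (any(bad)) stop("target deltas must lie in (-1, 1)", call. = FALSE)
  structure(
    list(n_respondents = as.integer(n_respondents),
         condition_sizes = condition_sizes[conds],
         target_deltas = target_deltas,
         attention_fail_rate = attention_fail_rate,
         time_medians = time_medians, time_log_sd = time_log_sd,
         item_cutpoints = item_cutpoints, noise_scale = noise_scale,
         appraisal_probs = appraisal_probs, bank_spec = bank_spec),
    class = "synth_config"
  )
}

#' Default latent cutpoints of the four acceptability items
#'
#' Row `k` holds the four ordered cutpoints of item `k` on the latent
#' acceptability scale. Chosen so the control condition's item means are
#' roughly 3.2 ("interesting"), 3.3 ("satisfied with information"), 2.1
#' ("would share") and 2.9 ("would recommend") on 0-4, all positively
#' skewed.
#'
#' @return 4 x 4 numeric matrix.
#' @export
default_item_cutpoints <- function() {
  rbind(
    q1 = c(-5.69, -4.03, -2.47, 0.37),
    q2 = c(-5.92, -4.26, -2.70, 0.14),
    q3 = c(-3.53, -1.48, 0.97, 2.83),
    q4 = c(-5.49, -3.54, -1.29, 1.35)
  )
}

#' Default feedback-appraisal response distributions
#'
#' Category probabilities (responses 0-4) for the four appraisal items,
#' set so that agreement rates (categories 3-4) are about 82\% and 93\%
#' for graphical accuracy/clarity and 82\% and 95\% for text-based
#' accuracy/clarity.
#'
#' @return Named list of probability vectors.
#' @export
default_appraisal_probs <- function() {
  list(
    graph_accurate = c(0.040, 0.050, 0.086, 0.404, 0.420),
    graph_clear    = c(0.012, 0.017, 0.042, 0.399, 0.530),
    text_accurate  = c(0.046, 0.060, 0.075, 0.409, 0.410),
    text_clear     = c(0.006, 0.009, 0.034, 0.411, 0.540)
  )
}

feedback_conditions <- c("fixed_graphical", "fixed_graphical_text",
                         "cat_graphical", "cat_graphical_text")
text_conditions <- c("fixed_graphical_text", "cat_graphical_text")

# ---- population distributions over the finite total-score support ----------

# Conditional pmf of one item given latent a: P(X >= c) = plogis((a - c)/s).
item_pmf_given_a <- function(a, cutpoints, noise_scale) {
  surv <- stats::plogis((a - cutpoints) / noise_scale)
  c(1, surv) - c(surv, 0)
}

#' Population distribution of the acceptability total score
#'
#' Exact (to quadrature accuracy) pmf of the 0-16 total of the four
#' acceptability items for a condition whose latent acceptability is
#' logistic with location `shift` and scale 1. The four items are
#' conditionally independent given the latent value, each discretized by
#' its cutpoints after adding logistic noise; the marginal total pmf is
#' obtained by convolving the conditional item pmfs and integrating over
#' the latent density on a fine grid.
#'
#' @param shift Latent location of the condition (0 = control).
#' @param config A [synth_config()] (only `item_cutpoints` and
#'   `noise_scale` are used).
#' @param grid_step,grid_halfwidth Quadrature grid resolution and
#'   half-range.
#' @return Numeric vector of length 17 (totals 0-16) summing to 1.
#' @export
population_total_pmf <- function(shift, config = synth_config(),
                                 grid_step = 0.05, grid_halfwidth = 16) {
  a <- seq(shift - grid_halfwidth, shift + grid_halfwidth, by = grid_step)
  wts <- stats::dlogis(a, location = shift)
  wts <- wts / sum(wts)
  pmf <- numeric(17L)
  for (g in seq_along(a)) {
    tot <- 1
    for (k in 1:4) {
      tot <- convolve_pmf(tot, item_pmf_given_a(a[g], config$item_cutpoints[k, ],
                                                config$noise_scale))
    }
    pmf <- pmf + wts[g] * tot
  }
  pmf
}

convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

#' Population Cliff's delta between two discrete distributions
#'
#' Brute-force evaluation of `P(X > Y) - P(X < Y)` for two pmfs on the
#' same finite ordered support -- the quantity the generator's
#' calibration targets.
#'
#' @param pmf_x,pmf_y Probability vectors over the same support.
#' @return Scalar in `[-1, 1]`.
#' @export
population_delta <- function(pmf_x, pmf_y) {
  stopifnot(length(pmf_x) == length(pmf_y))
  d <- 0
  for (t in seq_along(pmf_x)) {
    for (u in seq_along(pmf_y)) {
      d <- d + pmf_x[t] * pmf_y[u] * sign(t - u)
    }
  }
  d
}

# Calibrate a latent shift so the condition's population delta vs a
# reference pmf equals `target`. Monotone in the shift, so uniroot.
calibrate_shift <- function(target, ref_pmf, config, interval = c(-4, 4)) {
  f <- function(mu) {
    population_delta(population_total_pmf(mu, config), ref_pmf) - target
  }
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo > 0 || hi < 0) {
    stop(sprintf(
      "target delta %.3f unattainable; achievable range is [%.3f, %.3f]",
      target, lo + target, hi + target), call. = FALSE)
  }
  stats::uniroot(f, interval, tol = 1e-7)$root
}

#' Calibrated latent shifts for all six conditions
#'
#' Resolves the `target_deltas` of a [synth_config()] into per-condition
#' latent location shifts. The fixed/none control is pinned at 0. Named
#' per-condition targets are calibrated one at a time against the
#' control's total-score pmf; the special `pooled_graphical_text` target
#' assigns both graphical_text arms a single common shift calibrated so
#' that the size-weighted pooled graphical_text distribution attains the
#' target delta against the size-weighted pooled no-feedback
#' distribution. Conditions without a target keep shift 0.
#'
#' @param config A [synth_config()].
#' @return Named numeric vector of shifts for the six conditions.
#' @export
calibrate_condition_shifts <- function(config) {
  conds <- names(config$condition_sizes)
  shifts <- stats::setNames(numeric(length(conds)), conds)
  ref <- population_total_pmf(0, config)
  targets <- config$target_deltas
  for (nm in setdiff(names(targets), "pooled_graphical_text")) {
    if (!nm %in% conds) {
      stop("unknown target_deltas entry: ", nm, call. = FALSE)
    }
    if (nm == "fixed_none") stop("the control condition cannot carry a target",
                                 call. = FALSE)
    shifts[nm] <- if (targets[[nm]] == 0) 0 else
      calibrate_shift(targets[[nm]], ref, config)
  }
  if (!is.null(targets$pooled_graphical_text)) {
    w <- config$condition_sizes[c("fixed_none", "cat_none")]
    pooled_none <- (w[1] * ref +
                    w[2] * population_total_pmf(shifts["cat_none"], config)) /
                   sum(w)
    tgt <- targets$pooled_graphical_text
    mu <- if (tgt == 0 && all(shifts[c("fixed_none", "cat_none")] == 0)) 0 else
      calibrate_shift(tgt, pooled_none, config)
    shifts[text_conditions] <- mu
  }
  shifts
}

# ---- record-level generation ----------------------------------------------

#' Generate a synthetic six-condition acceptability survey
#'
#' Draws one record per respondent: condition assignment (proportional
#' to the configured condition sizes), four ordinal acceptability items
#' (0-4) from a shifted logistic latent with per-item cutpoints and
#' noise, their 0-16 total, an attention-check failure flag, log-normal
#' feedback-viewing seconds for feedback conditions, and 0-4
#' feedback-appraisal items (graphical items for all feedback
#' conditions, text items for the graphical_text conditions only).
#' Latent shifts are calibrated to the configured population Cliff's
#' deltas by [calibrate_condition_shifts()].
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @param shifts Optional precomputed result of
#'   [calibrate_condition_shifts()] for this `config`; supply it when
#'   generating many replicates to avoid re-running the calibration.
#' @return List with `records` (data.frame: respondent_id, condition,
#'   q1-q4, total, attention_failed, feedback_seconds, graph_accurate,
#'   graph_clear, text_accurate, text_clear) and `shifts` (the
#'   calibrated latent shifts).
#' @export
generate_acceptability <- function(config = synth_config(), seed = 1L,
                                   shifts = NULL) {
  if (is.null(shifts)) shifts <- calibrate_condition_shifts(config)
  set.seed(seed)
  sizes <- config$condition_sizes
  alloc <- proportional_allocation(sizes, config$n_respondents)
  condition <- rep(names(sizes), times = alloc)
  n <- length(condition)
  latent <- stats::rlogis(n, location = shifts[condition], scale = 1)
  items <- matrix(NA_integer_, n, 4L,
                  dimnames = list(NULL, paste0("q", 1:4)))
  for (k in 1:4) {
    noise <- stats::rlogis(n, 0, config$noise_scale)
    items[, k] <- rowSums(outer(latent + noise, config$item_cutpoints[k, ],
                                `>`))
  }
  attention_failed <- stats::runif(n) < config$attention_fail_rate
  feedback_seconds <- rep(NA_real_, n)
  for (fc in feedback_conditions) {
    idx <- condition == fc
    feedback_seconds[idx] <- stats::rlnorm(
      sum(idx), meanlog = log(config$time_medians[[fc]]),
      sdlog = config$time_log_sd)
  }
  appr <- matrix(NA_integer_, n, 4L,
                 dimnames = list(NULL, names(config$appraisal_probs)))
  graph_idx <- condition %in% feedback_conditions
  text_idx <- condition %in% text_conditions
  for (nm in names(config$appraisal_probs)) {
    idx <- if (startsWith(nm, "text")) text_idx else graph_idx
    appr[idx, nm] <- sample(0:4, sum(idx), replace = TRUE,
                            prob = config$appraisal_probs[[nm]])
  }
  records <- data.frame(
    respondent_id = sprintf("r%04d", seq_len(n)),
    condition = condition,
    items,
    total = rowSums(items),
    attention_failed = attention_failed,
    feedback_seconds = feedback_seconds,
    appr,
    stringsAsFactors = FALSE
  )
  list(records = records, shifts = shifts)
}

# Largest-remainder allocation of n across the named sizes.
proportional_allocation <- function(sizes, n) {
  raw <- sizes / sum(sizes) * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(sizes))
}

# ---- item bank and item-response generation --------------------------------

#' Generate a synthetic adaptive item bank
#'
#' Per domain, `n_items_per_domain` polytomous items whose difficulty
#' centers are evenly spaced across `center_range`; each item's
#' `n_steps` thresholds are the center plus evenly spaced step offsets
#' spanning `+/- step_spread`, perturbed by Gaussian jitter. The bank is
#' a deterministic function of `(spec, seed)` and stands in for a
#' calibrated quality-of-life item bank, which is not redistributable.
#'
#' @param spec Bank specification (see [synth_config()]'s `bank_spec`).
#' @param seed Integer seed.
#' @return An [item_bank()].
#' @export
generate_bank <- function(spec = synth_config()$bank_spec, seed = 1L) {
  set.seed(seed)
  items <- list()
  n_per <- rep_len(spec$n_items_per_domain, length(spec$domains))
  for (di in seq_along(spec$domains)) {
    d <- spec$domains[di]
    n_items <- n_per[di]
    centers <- if (n_items == 1L) {
      mean(spec$center_range)
    } else {
      seq(spec$center_range[1], spec$center_range[2], length.out = n_items)
    }
    offsets <- if (spec$n_steps == 1L) 0 else {
      seq(-spec$step_spread, spec$step_spread, length.out = spec$n_steps)
    }
    for (i in seq_len(n_items)) {
      b <- centers[i] + offsets +
        stats::rnorm(spec$n_steps, 0, spec$threshold_jitter_sd)
      items[[length(items) + 1L]] <- pcm_item(
        sprintf("%s_%02d", substr(d, 1, 4), i), d, b)
    }
  }
  item_bank(items)
}

#' Simulate item responses from known latent traits
#'
#' Draws each respondent's latent trait per domain from a standard
#' normal and samples every item response from the partial credit model
#' at that trait value. The true traits are returned alongside the
#' responses so estimator recovery can be measured.
#'
#' @param bank An [item_bank()].
#' @param n Number of respondents.
#' @param seed Integer seed.
#' @param thetas Optional matrix of true traits (respondents x domains,
#'   columns named by domain); drawn `N(0, 1)` when `NULL`.
#' @return List with `responses` (n x items integer matrix, columns
#'   named by item id) and `thetas` (n x domains matrix).
#' @export
generate_respondents <- function(bank, n, seed = 1L, thetas = NULL) {
  set.seed(seed)
  domains <- bank_domains(bank)
  if (is.null(thetas)) {
    thetas <- matrix(stats::rnorm(n * length(domains)), nrow = n,
                     ncol = length(domains), dimnames = list(NULL, domains))
  }
  ids <- names(bank$items)
  responses <- matrix(NA_integer_, n, length(ids),
                      dimnames = list(NULL, ids))
  if (n == 0L) return(list(responses = responses, thetas = thetas))
  for (id in ids) {
    item <- bank$items[[id]]
    th <- thetas[, item$domain_id]
    k <- 0:length(item$thresholds)
    B <- c(0, cumsum(item$thresholds))
    L <- outer(th, k) - rep(B, each = n)
    mx <- apply(L, 1L, max)
    P <- exp(L - mx)
    P <- P / rowSums(P)
    u <- stats::runif(n)
    cum <- t(apply(P, 1L, cumsum))
    responses[, id] <- as.integer(rowSums(u > cum))
  }
  list(responses = responses, thetas = thetas)
}
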