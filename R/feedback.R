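#' Classify a 0-100 domain score into a feedback band
#'
#' Scores are compared with the population-average score for the domain:
#' within `band_halfwidth` points of the norm (boundaries inclusive) the
#' score is `"average"`; below that band, `"lower"`; above it,
#' `"higher"`. The bands drive which tailored message a respondent sees.
#'
#' @param score Numeric score in `[0, 100]`.
#' @param norm_score Population mean on the same 0-100 scale.
#' @param band_halfwidth Half-width of the "average" band in scale
#'   points; default 5.
#' @return One of `"lower"`, `"average"`, `"higher"`.
#' @examples
#' assign_band(26, norm_score = 59)  # "lower"
#' @export
assign_band <- function(score, norm_score, band_halfwidth = 5) {
  if (!is.numeric(score) || score < 0 || score > 100) {
    stop("'score' must lie in [0, 100]", call. = FALSE)
  }
  if (score < norm_score - band_halfwidth) {
    "lower"
  } else if (score > norm_score + band_halfwidth) {
    "higher"
  } else {
    "average"
  }
}

band_levels <- c("lower", "average", "higher")

#' Default tailored-feedback message templates
#'
#' One template per (domain, band), with `{score}` and `{domain}`
#' placeholders interpolated at render time. The wording mirrors the
#' style of tailored QoL feedback — what the domain reflects, how the
#' score compares with the average, and what it might mean — without
#' reproducing any copyrighted instrument text.
#'
#' @param domains Character vector of domain ids the templates must
#'   cover.
#' @return Nested list: `templates[[domain]][[band]]` is a character
#'   template.
#' @export
default_feedback_templates <- function(domains = c("physical",
                                                   "psychological",
                                                   "social",
                                                   "environment")) {
  mk <- function(domain) list(
    lower = paste0(
      "Your score of {score} on this scale indicates that your {domain} ",
      "quality of life is lower than average. This suggests that your ",
      "satisfaction with this area of your life is lower than it could ",
      "be. You could discuss these things with your doctor."),
    average = paste0(
      "Your score of {score} on this scale indicates that your {domain} ",
      "quality of life is about average. Most people score in this ",
      "range; your satisfaction with this area of your life is typical."),
    higher = paste0(
      "Your score of {score} on this scale indicates that your {domain} ",
      "quality of life is higher than average. You appear satisfied ",
      "with this area of your life.")
  )
  stats::setNames(lapply(domains, mk), domains)
}

interpolate_template <- function(template, score, domain) {
  msg <- gsub("{score}", format(round(score), nsmall = 0), template,
              fixed = TRUE)
  gsub("{domain}", domain, msg, fixed = TRUE)
}

#' Render a feedback bundle for one respondent
#'
#' Deterministically assembles the material shown after an assessment,
#' per experimental condition: `"none"` produces an empty bundle;
#' `"graphical"` produces one horizontal 0-100 bar per domain;
#' `"graphical_text"` additionally attaches a tailored message per
#' domain, selected by [assign_band()] against the domain norm and
#' interpolated with the numeric score.
#'
#' @param scores Named numeric vector of 0-100 scores, one per domain
#'   (names are domain ids), or a list of `domain_score` objects.
#' @param condition One of `"none"`, `"graphical"`, `"graphical_text"`.
#' @param templates Message templates as from
#'   [default_feedback_templates()]; must cover every (domain, band)
#'   that can arise.
#' @param norms Named numeric vector of population-average 0-100 scores
#'   per domain.
#' @param band_halfwidth Passed to [assign_band()].
#' @return An object of class `feedback_bundle` with fields `condition`,
#'   `bars` (data.frame domain_id/score_0_100; empty for `"none"`) and
#'   `texts` (data.frame domain_id/band/message; empty unless
#'   `"graphical_text"`).
#' @export
render_feedback <- function(scores, condition = c("none", "graphical",
                                                  "graphical_text"),
                            templates = default_feedback_templates(names(scores)),
                            norms, band_halfwidth = 5) {
  condition <- match.arg(condition)
  if (is.list(scores) && all(vapply(scores, inherits, logical(1),
                                    "domain_score"))) {
    scores <- stats::setNames(
      vapply(scores, `[[`, numeric(1), "score_0_100"),
      vapply(scores, `[[`, character(1), "domain_id"))
  }
  domains <- names(scores)
  if (is.null(domains) || any(!nzchar(domains))) {
    stop("'scores' must be named by domain", call. = FALSE)
  }
  empty_bars <- data.frame(domain_id = character(), score_0_100 = numeric(),
                           stringsAsFactors = FALSE)
  empty_texts <- data.frame(domain_id = character(), band = character(),
                            message = character(), stringsAsFactors = FALSE)
  if (condition == "none") {
    return(structure(list(condition = condition, bars = empty_bars,
                          texts = empty_texts), class = "feedback_bundle"))
  }
  bars <- data.frame(domain_id = domains,
                     score_0_100 = unname(as.numeric(scores)),
                     stringsAsFactors = FALSE)
  texts <- empty_texts
  if (condition == "graphical_text") {
    if (missing(norms)) stop("'norms' required for tailored text",
                             call. = FALSE)
    rows <- lapply(domains, function(d) {
      if (is.na(norms[d])) {
        stop("no norm score for domain '", d, "'", call. = FALSE)
      }
      band <- assign_band(scores[[d]], norms[[d]], band_halfwidth)
      tpl <- templates[[d]][[band]]
      if (is.null(tpl)) {
        stop(sprintf("missing feedback template for (%s, %s)", d, band),
             call. = FALSE)
      }
      data.frame(domain_id = d, band = band,
                 message = interpolate_template(tpl, scores[[d]], d),
                 stringsAsFactors = FALSE)
    })
    texts <- do.call(rbind, rows)
  }
  structure(list(condition = condition, bars = bars, texts = texts),
            class = "feedback_bundle")
}

#' @export
print.feedback_bundle <- function(x, ...) {
  cat(sprintf("Feedback bundle (%s)\n", x$condition))
  if (nrow(x$bars)) {
    for (i in seq_len(nrow(x$bars))) {
      sc <- x$bars$score_0_100[i]
      bar <- strrep("#", round(sc / 5))
      cat(sprintf("  %-14s %-20s %5.1f\n", x$bars$domain_id[i], bar, sc))
    }
  }
  if (nrow(x$texts)) {
    for (i in seq_len(nrow(x$texts))) {
      cat(sprintf("  [%s/%s] %s\n", x$texts$domain_id[i], x$texts$band[i],
                  x$texts$message[i]))
    }
  }
  invisible(x)
}

#' @export
plot.feedback_bundle <- function(x, ...) {
  if (!nrow(x$bars)) {
    stop("nothing to plot: condition '", x$condition, "' has no bars",
         call. = FALSE)
  }
  graphics::barplot(rev(x$bars$score_0_100), names.arg = rev(x$bars$domain_id),
                    horiz = TRUE, xlim = c(0, 100), las = 1,
                    xlab = "Score (0 = worst, 100 = best quality of life)",
                    ...)
  invisible(x)
}
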