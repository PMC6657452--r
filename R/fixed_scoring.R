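#' Define a fixed-length questionnaire form
#'
#' Metadata for scoring a fixed-length ordinal questionnaire in the
#' WHOQOL-BREF style: items grouped into domains, responses on a
#' `1..n_categories` scale, some items reverse-keyed.
#'
#' @param items Data frame with columns `item_id`, `domain_id`,
#'   `n_categories` (>= 2) and logical `reversed`. Every domain must have
#'   at least 3 items.
#' @param missing_tolerance Maximum fraction of missing items per domain
#'   before the domain score is declared missing (default 0.2, the usual
#'   guideline of at most 20% unanswered).
#' @return An object of class `fixed_form`.
#' @export
fixed_form <- function(items, missing_tolerance = 0.2) {
  req <- c("item_id", "domain_id", "n_categories", "reversed")
  if (!is.data.frame(items) || !all(req %in% names(items))) {
    stop("'items' needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(items$n_categories < 2)) {
    stop("each item needs n_categories >= 2", call. = FALSE)
  }
  if (anyDuplicated(items$item_id)) stop("duplicate item_id", call. = FALSE)
  cnt <- table(items$domain_id)
  if (any(cnt < 3)) {
    stop("every domain needs >= 3 items; short: ",
         paste(names(cnt)[cnt < 3], collapse = ", "), call. = FALSE)
  }
  if (missing_tolerance < 0 || missing_tolerance >= 1) {
    stop("'missing_tolerance' must be in [0, 1)", call. = FALSE)
  }
  structure(list(items = items, missing_tolerance = missing_tolerance),
            class = "fixed_form")
}

#' Score a fixed-length form on the 0-100 scale
#'
#' Reverse-keyed items are recoded (`x -> n_categories + 1 - x`), the
#' per-domain mean of non-missing responses is taken when the missing
#' fraction does not exceed the form's tolerance, and the mean is mapped
#' linearly to 0-100: `(mean - 1) / (n_categories - 1) * 100`. The
#' guideline 4-20 intermediate (`mean * 4`, defined for 5-category
#' domains) is also returned for parity with published scoring syntax.
#'
#' @param form A [fixed_form()].
#' @param responses Data frame or matrix, one row per respondent, one
#'   column per `item_id` of the form (a `respondent_id` column is
#'   carried through if present). Entries are `1..n_categories` or `NA`.
#' @return Data frame with `respondent_id`, one `score_<domain>` column
#'   (0-100, `NA` when too many items are missing) and one
#'   `raw_4_20_<domain>` column per domain.
#' @examples
#' f <- fixed_form(data.frame(
#'   item_id = paste0("q", 1:6), domain_id = rep(c("a", "b"), each = 3),
#'   n_categories = 5, reversed = FALSE))
#' r <- data.frame(q1 = 5, q2 = 5, q3 = 5, q4 = 1, q5 = 1, q6 = 1)
#' score_fixed_form(f, r)
#' @export
score_fixed_form <- function(form, responses) {
  responses <- as.data.frame(responses)
  ids <- if ("respondent_id" %in% names(responses)) {
    responses$respondent_id
  } else {
    seq_len(nrow(responses))
  }
  miss_item <- setdiff(form$items$item_id, names(responses))
  if (length(miss_item)) {
    stop("responses lack item column(s): ",
         paste(miss_item, collapse = ", "), call. = FALSE)
  }
  # validate and recode once, per item
  rec <- matrix(NA_real_, nrow(responses), nrow(form$items),
                dimnames = list(NULL, form$items$item_id))
  for (i in seq_len(nrow(form$items))) {
    it <- form$items[i, ]
    x <- responses[[it$item_id]]
    bad <- which(!is.na(x) & (x < 1 | x > it$n_categories | x != round(x)))
    if (length(bad)) {
      stop(sprintf("out-of-range response for respondent '%s', item '%s'",
                   ids[bad[1]], it$item_id), call. = FALSE)
    }
    rec[, i] <- if (it$reversed) it$n_categories + 1 - x else x
  }
  domains <- unique(form$items$domain_id)
  out <- data.frame(respondent_id = ids)
  for (d in domains) {
    cols <- form$items$item_id[form$items$domain_id == d]
    sub <- rec[, cols, drop = FALSE]
    n_miss <- rowSums(is.na(sub))
    ok <- n_miss / length(cols) <= form$missing_tolerance
    dmean <- ifelse(ok, rowMeans(sub, na.rm = TRUE), NA_real_)
    ncat <- form$items$n_categories[form$items$domain_id == d][1]
    out[[paste0("score_", d)]] <- (dmean - 1) / (ncat - 1) * 100
    out[[paste0("raw_4_20_", d)]] <- dmean * 4
  }
  out
}
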