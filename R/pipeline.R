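#' Exclude respondents who failed the attention check
#'
#' Drops records whose `attention_failed` flag is set, preserving order.
#'
#' @param records Data frame with a logical `attention_failed` column.
#' @return List with `kept` (data.frame) and `excluded_count`.
#' @export
filter_attention <- function(records) {
  if (!"attention_failed" %in% names(records)) {
    stop("records must carry an 'attention_failed' flag", call. = FALSE)
  }
  keep <- !records$attention_failed
  list(kept = records[keep, , drop = FALSE],
       excluded_count = sum(!keep))
}

#' Agree/neutral/disagree breakdown of a feedback-appraisal item
#'
#' Collapses a 0-4 Likert item into disagree (0-1), neutral (2) and
#' agree (3-4), with counts and percentages of the non-missing responses
#' (rounded to one decimal).
#'
#' @param records Data frame holding the item column.
#' @param item Column name of the appraisal item.
#' @return List with `n` and per-category `*_n` / `*_pct` fields.
#' @export
appraisal_table <- function(records, item) {
  x <- records[[item]]
  if (is.null(x)) stop("no column '", item, "' in records", call. = FALSE)
  x <- x[!is.na(x)]
  if (!length(x)) stop("no responses for item '", item, "'", call. = FALSE)
  if (any(x < 0 | x > 4 | x != round(x))) {
    stop("appraisal responses must be on the 0-4 scale", call. = FALSE)
  }
  n <- length(x)
  cnt <- c(disagree = sum(x <= 1), neutral = sum(x == 2), agree = sum(x >= 3))
  pct <- round(cnt / n * 100, 1)
  list(item = item, n = n,
       disagree_n = unname(cnt["disagree"]), disagree_pct = unname(pct["disagree"]),
       neutral_n = unname(cnt["neutral"]), neutral_pct = unname(pct["neutral"]),
       agree_n = unname(cnt["agree"]), agree_pct = unname(pct["agree"]))
}

#' Item-count reduction of adaptive relative to fixed-length assessment
#'
#' @param items_administered Numeric vector: total items administered to
#'   each respondent across all domains (or a list of `cat_session`s,
#'   whose counts are summed).
#' @param fixed_length Length of the fixed-length comparator (default
#'   24).
#' @return List with `mean_items`, `sd_items`, `pct_reduction` (one
#'   decimal, `(fixed - mean)/fixed * 100`).
#' @examples
#' item_reduction(c(17, 18, 19), fixed_length = 24)
#' @export
item_reduction <- function(items_administered, fixed_length = 24L) {
  if (is.list(items_administered)) {
    items_administered <- vapply(items_administered,
                                 function(s) nrow(s$administered), numeric(1))
  }
  if (!length(items_administered)) stop("no sessions", call. = FALSE)
  if (fixed_length <= 0) stop("'fixed_length' must be positive", call. = FALSE)
  m <- mean(items_administered)
  list(mean_items = m,
       sd_items = stats::sd(items_administered),
       fixed_length = fixed_length,
       pct_reduction = round((fixed_length - m) / fixed_length * 100, 1))
}

#' Default fixed-length form of the synthetic study
#'
#' A 24-item, four-domain form in the WHOQOL-BREF layout (7 physical, 6
#' psychological, 3 social, 8 environment items; 5 response categories),
#' with three reverse-keyed items.
#'
#' @return A [fixed_form()].
#' @export
default_fixed_form <- function() {
  counts <- c(physical = 7L, psychological = 6L, social = 3L,
              environment = 8L)
  items <- do.call(rbind, lapply(names(counts), function(d) {
    data.frame(item_id = sprintf("%s_f%02d", substr(d, 1, 4),
                                 seq_len(counts[[d]])),
               domain_id = d, n_categories = 5L, reversed = FALSE,
               stringsAsFactors = FALSE)
  }))
  items$reversed[items$item_id %in% c("phys_f03", "phys_f04", "psyc_f05")] <- TRUE
  fixed_form(items)
}

# Per-condition two-group comparison: Cliff's delta + Wilcoxon + verdict.
compare_groups <- function(x, y) {
  p <- wilcoxon_rank_sum(x, y)
  cliffs_delta(x, y, p_value = p)
}

effect_row <- function(label, variable, x, y) {
  es <- compare_groups(x, y)
  data.frame(comparison = label, variable = variable,
             n = es$n_x, n_ref = es$n_y,
             mean = mean(x), sd = stats::sd(x),
             mean_ref = mean(y), sd_ref = stats::sd(y),
             delta = es$delta, ci_low = es$ci_low, ci_high = es$ci_high,
             p_value = es$p_value, verdict = es$verdict,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic study analogue
#'
#' End-to-end orchestration of the six-condition experiment: generate
#' the acceptability survey, exclude attention-check failures, compute
#' the effect-size table of every condition against the fixed-length /
#' no-feedback control (total score and the four items) plus the pooled
#' feedback contrasts, assess the acceptability scale (Mokken H,
#' Cronbach's alpha), tabulate feedback appraisal and viewing times
#' (compared against the fixed-length/graphical reference), simulate the
#' adaptive assessment to measure item usage and score both forms on the
#' 0-100 scale, and render feedback bundles for the feedback conditions.
#'
#' @param config A [synth_config()].
#' @param seed Integer master seed; every stage derives its stream from
#'   it, so the report is a pure function of `(config, seed)`.
#' @param cat A [cat_config()]; its norms default to the generator's
#'   trait distribution (standard normal per domain).
#' @param fixed_length Item count of the fixed-length comparator
#'   (default 24).
#' @param cat_sim_n Number of adaptive sessions to simulate; defaults to
#'   the number of analyzed respondents in the adaptive arms.
#' @return An object of class `qol_study`; see the fields in the
#'   examples and the print/summary methods.
#' @export
run_study <- function(config = synth_config(), seed = 1L,
                      cat = NULL, fixed_length = 24L, cat_sim_n = NULL) {
  domains <- config$bank_spec$domains
  if (is.null(cat)) {
    cat <- cat_config(norms = stats::setNames(
      rep(list(list(mean = 0, sd = 1)), length(domains)), domains))
  }
  acc <- generate_acceptability(config, seed)
  filt <- filter_attention(acc$records)
  kept <- filt$kept
  n_enrolled <- nrow(acc$records)
  n_excluded <- filt$excluded_count
  n_analyzed <- nrow(kept)

  ctrl <- kept[kept$condition == "fixed_none", , drop = FALSE]
  others <- setdiff(names(config$condition_sizes), "fixed_none")
  vars <- c("total", paste0("q", 1:4))
  table2 <- do.call(rbind, lapply(others, function(cc) {
    grp <- kept[kept$condition == cc, , drop = FALSE]
    do.call(rbind, lapply(vars, function(v) {
      effect_row(paste0(cc, " vs fixed_none"), v, grp[[v]], ctrl[[v]])
    }))
  }))
  pooled_gt <- kept$total[kept$condition %in% text_conditions]
  pooled_gr <- kept$total[kept$condition %in% c("fixed_graphical",
                                                "cat_graphical")]
  pooled_none <- kept$total[kept$condition %in% c("fixed_none", "cat_none")]
  table2_pooled <- rbind(
    effect_row("pooled graphical_text vs pooled none", "total",
               pooled_gt, pooled_none),
    effect_row("pooled graphical vs pooled none", "total",
               pooled_gr, pooled_none))

  scale_items <- as.matrix(kept[, paste0("q", 1:4)])
  mokken <- loevinger_h(scale_items)
  reliability <- cronbach_alpha(scale_items)

  table3 <- lapply(names(config$appraisal_probs),
                   function(it) appraisal_table(kept, it))
  names(table3) <- names(config$appraisal_probs)

  ref_time <- kept$feedback_seconds[kept$condition == "fixed_graphical"]
  table4 <- do.call(rbind, lapply(feedback_conditions, function(cc) {
    secs <- kept$feedback_seconds[kept$condition == cc]
    row <- data.frame(condition = cc, n = length(secs),
                      median_seconds = stats::median(secs),
                      delta = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      verdict = NA_character_, stringsAsFactors = FALSE)
    if (cc != "fixed_graphical") {
      es <- compare_groups(secs, ref_time)
      row$delta <- es$delta; row$ci_low <- es$ci_low
      row$ci_high <- es$ci_high; row$p_value <- es$p_value
      row$verdict <- es$verdict
    }
    row
  }))

  # adaptive assessment simulation for the adaptive-arm sample size
  bank <- generate_bank(config$bank_spec, seed = derive_seed(seed, 1L))
  n_cat <- if (is.null(cat_sim_n)) {
    sum(kept$condition %in% c("cat_none", "cat_graphical",
                              "cat_graphical_text"))
  } else {
    cat_sim_n
  }
  set.seed(derive_seed(seed, 2L))
  cat_thetas <- matrix(stats::rnorm(n_cat * length(domains)), nrow = n_cat,
                       dimnames = list(NULL, domains))
  cat_scores <- matrix(NA_real_, n_cat, length(domains),
                       dimnames = list(NULL, domains))
  items_per_respondent <- numeric(n_cat)
  for (r in seq_len(n_cat)) {
    tot <- 0L
    for (d in domains) {
      ses <- run_cat(bank, pcm_responder(cat_thetas[r, d]), cat, d)
      tot <- tot + nrow(ses$administered)
      cat_scores[r, d] <-
        theta_to_domain_score(ses$final, cat, d)$score_0_100
    }
    items_per_respondent[r] <- tot
  }
  cat_summary <- item_reduction(items_per_respondent, fixed_length)

  # fixed-length arm: generate and score the 24-item form
  form <- default_fixed_form()
  n_fixed <- sum(kept$condition %in% c("fixed_none", "fixed_graphical",
                                       "fixed_graphical_text"))
  form_domains <- unique(form$items$domain_id)
  fixed_bank <- generate_bank(
    list(domains = form_domains,
         n_items_per_domain = as.integer(table(form$items$domain_id)[form_domains]),
         n_steps = 4L, center_range = c(-1.5, 1.5),
         step_spread = config$bank_spec$step_spread,
         threshold_jitter_sd = config$bank_spec$threshold_jitter_sd),
    seed = derive_seed(seed, 3L))
  gen <- generate_respondents(fixed_bank, n_fixed,
                              seed = derive_seed(seed, 4L))
  resp <- as.data.frame(gen$responses + 1L)          # categories 1..5
  # bank items are emitted domain by domain in the form's row order
  names(resp) <- form$items$item_id
  for (i in seq_len(nrow(form$items))) {             # emit raw reversed keys
    if (form$items$reversed[i]) {
      id <- form$items$item_id[i]
      resp[[id]] <- form$items$n_categories[i] + 1L - resp[[id]]
    }
  }
  fixed_scores <- score_fixed_form(form, resp)

  score_cols <- paste0("score_", domains)
  table1 <- data.frame(
    domain = domains,
    fixed_mean = vapply(score_cols, function(cn) mean(fixed_scores[[cn]],
                                                      na.rm = TRUE), numeric(1)),
    fixed_sd = vapply(score_cols, function(cn) stats::sd(fixed_scores[[cn]],
                                                         na.rm = TRUE), numeric(1)),
    cat_mean = colMeans(cat_scores),
    cat_sd = apply(cat_scores, 2L, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )

  # feedback bundles for the feedback conditions (norm score 50 = the
  # reference-population mean under the norm model)
  norms_0_100 <- stats::setNames(rep(50, length(domains)), domains)
  example_scores <- stats::setNames(as.numeric(cat_scores[1L, ]), domains)
  example_feedback <- render_feedback(example_scores, "graphical_text",
                                      norms = norms_0_100)
  band_counts <- table(factor(vapply(seq_len(nrow(cat_scores)), function(r) {
    assign_band(cat_scores[r, 1L], norms_0_100[1L])
  }, character(1)), levels = band_levels))

  structure(
    list(seed = seed, n_enrolled = n_enrolled, n_excluded = n_excluded,
         n_analyzed = n_analyzed,
         condition_ns = table(kept$condition)[names(config$condition_sizes)],
         shifts = acc$shifts,
         table1 = table1, table2 = table2, table2_pooled = table2_pooled,
         mokken = mokken, reliability = reliability,
         table3 = table3, table4 = table4,
         cat_summary = cat_summary,
         example_feedback = example_feedback,
         band_counts = band_counts),
    class = "qol_study"
  )
}

# Deterministic sub-stream seeds below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1000L + 7L * as.integer(k)) %% 2147483629L
}

#' @export
print.qol_study <- function(x, ...) {
  cat("Synthetic QoL assessment experiment\n")
  cat(sprintf("  enrolled %d, excluded %d (attention check), analyzed %d\n",
              x$n_enrolled, x$n_excluded, x$n_analyzed))
  cat(sprintf("  acceptability scale: Loevinger H = %.2f (%s), alpha = %.2f\n",
              x$mokken$scale_h, x$mokken$classification,
              x$reliability$alpha))
  p <- x$table2_pooled
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %s: delta = %.2f (%.2f to %.2f), P = %.3g (%s)\n",
                p$comparison[i], p$delta[i], p$ci_low[i], p$ci_high[i],
                p$p_value[i], p$verdict[i]))
  }
  cat(sprintf("  adaptive test: mean %.1f items (SD %.1f) vs %d fixed -> %.1f%% reduction\n",
              x$cat_summary$mean_items, x$cat_summary$sd_items,
              x$cat_summary$fixed_length, x$cat_summary$pct_reduction))
  invisible(x)
}

#' @export
summary.qol_study <- function(object, ...) {
  print(object)
  cat("\nPer-condition comparisons vs fixed_none (total score):\n")
  t2 <- object$table2[object$table2$variable == "total", ]
  for (i in seq_len(nrow(t2))) {
    cat(sprintf("  %-38s mean %5.2f (SD %.2f) delta %+.2f  P %.3g (%s)\n",
                t2$comparison[i], t2$mean[i], t2$sd[i], t2$delta[i],
                t2$p_value[i], t2$verdict[i]))
  }
  cat("\nFeedback appraisal (agree %):\n")
  for (nm in names(object$table3)) {
    t3 <- object$table3[[nm]]
    cat(sprintf("  %-14s n = %4d  agree %.1f%%  neutral %.1f%%  disagree %.1f%%\n",
                nm, t3$n, t3$agree_pct, t3$neutral_pct, t3$disagree_pct))
  }
  cat("\nFeedback viewing time:\n")
  t4 <- object$table4
  for (i in seq_len(nrow(t4))) {
    extra <- if (is.na(t4$delta[i])) " (reference)" else
      sprintf("  delta %+.2f  P %.3g (%s)", t4$delta[i], t4$p_value[i],
              t4$verdict[i])
    cat(sprintf("  %-22s median %5.0f s%s\n", t4$condition[i],
                t4$median_seconds[i], extra))
  }
  invisible(object)
}

#' Serialize a study report to JSON
#'
#' @param report A `qol_study` object from [run_study()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  out <- list(
    seed = report$seed,
    n_enrolled = report$n_enrolled, n_excluded = report$n_excluded,
    n_analyzed = report$n_analyzed,
    condition_ns = as.list(report$condition_ns),
    scale = list(loevinger_h = report$mokken$scale_h,
                 classification = report$mokken$classification,
                 cronbach_alpha = report$reliability$alpha),
    table1 = report$table1,
    table2 = report$table2,
    table2_pooled = report$table2_pooled,
    table3 = report$table3,
    table4 = report$table4,
    cat_summary = report$cat_summary
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
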