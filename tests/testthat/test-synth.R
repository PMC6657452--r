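test_that("bank generation is deterministic and respects the spec", {
  spec <- synth_config()$bank_spec
  b1 <- generate_bank(spec, seed = 9)
  b2 <- generate_bank(spec, seed = 9)
  expect_identical(b1, b2)
  expect_length(b1$items, 25 * 4)
  for (d in spec$domains) expect_length(bank_items(b1, d), 25)

  degen <- generate_bank(list(domains = "d", n_items_per_domain = 5L,
                              n_steps = 3L, center_range = c(0, 0),
                              step_spread = 0, threshold_jitter_sd = 0),
                         seed = 1)
  ths <- lapply(degen$items, `[[`, "thresholds")
  expect_true(all(vapply(ths, identical, logical(1), ths[[1]])))
})

test_that("simulated responses follow the model probabilities", {
  spec <- list(domains = "d", n_items_per_domain = 3L, n_steps = 4L,
               center_range = c(-1, 1), step_spread = 0.25,
               threshold_jitter_sd = 0.15)
  bank <- generate_bank(spec, seed = 2)
  empty <- generate_respondents(bank, 0, seed = 3)
  expect_equal(nrow(empty$responses), 0)

  gen <- generate_respondents(bank, 400, seed = 4)
  expect_true(all(gen$responses >= 0 & gen$responses <= 4))

  # pin every trait at 0 and compare empirical category frequencies of
  # one item with its pmf, within 3 binomial SEs
  n <- 1e5
  th0 <- matrix(0, n, 1, dimnames = list(NULL, "d"))
  gen0 <- generate_respondents(bank, n, seed = 5, thetas = th0)
  item <- bank$items[[1]]
  p <- pcm_category_probs(item, 0)
  emp <- tabulate(gen0$responses[, item$item_id] + 1L, nbins = 5) / n
  # 4-SE band: five simultaneous binomial comparisons
  for (k in 1:5) {
    expect_lt(abs(emp[k] - p[k]), 4 * sqrt(p[k] * (1 - p[k]) / n))
  }
})

test_that("population machinery: pmfs normalize and delta is antisymmetric", {
  cfg <- synth_config()
  p0 <- population_total_pmf(0, cfg)
  p1 <- population_total_pmf(0.4, cfg)
  expect_length(p0, 17)
  expect_lt(abs(sum(p0) - 1), 1e-9)
  expect_equal(population_delta(p0, p1), -population_delta(p1, p0))
  expect_equal(population_delta(p0, p0), 0)
  expect_gt(population_delta(p1, p0), 0)
})

test_that("latent shifts are calibrated to the target population deltas", {
  cfg <- synth_config()
  shifts <- calibrate_condition_shifts(cfg)
  ref <- population_total_pmf(0, cfg)
  expect_equal(shifts[["fixed_none"]], 0)
  for (nm in c("fixed_graphical", "cat_none", "cat_graphical")) {
    realized <- population_delta(population_total_pmf(shifts[[nm]], cfg), ref)
    expect_lt(abs(realized - cfg$target_deltas[[nm]]), 0.01)
  }
  w <- cfg$condition_sizes[c("fixed_none", "cat_none")]
  pooled_none <- (w[[1]] * ref +
                  w[[2]] * population_total_pmf(shifts[["cat_none"]], cfg)) /
                 sum(w)
  pooled_gt <- population_total_pmf(shifts[["fixed_graphical_text"]], cfg)
  expect_lt(abs(population_delta(pooled_gt, pooled_none) - 0.22), 0.01)
  expect_equal(shifts[["fixed_graphical_text"]],
               shifts[["cat_graphical_text"]])

  expect_error(calibrate_shift(0.9999, ref, cfg), "achievable range")
})

test_that("survey generation is seed-reproducible with coherent records", {
  cfg <- small_synth_config()
  shifts <- calibrate_condition_shifts(cfg)
  a <- generate_acceptability(cfg, seed = 7, shifts = shifts)
  b <- generate_acceptability(cfg, seed = 7, shifts = shifts)
  expect_identical(a, b)
  rec <- a$records
  expect_equal(nrow(rec), 360)
  expect_equal(rec$total, rowSums(rec[, paste0("q", 1:4)]))
  expect_true(all(rec$total >= 0 & rec$total <= 16))
  none <- rec$condition %in% c("fixed_none", "cat_none")
  expect_true(all(is.na(rec$feedback_seconds[none])))
  expect_true(all(!is.na(rec$feedback_seconds[!none])))
  expect_true(all(is.na(rec$text_accurate[
    !rec$condition %in% c("fixed_graphical_text", "cat_graphical_text")])))

  quiet <- generate_acceptability(
    small_synth_config(attention_fail_rate = 0), seed = 8, shifts = shifts)
  expect_equal(sum(quiet$records$attention_failed), 0)
})

test_that("null targets produce null samples and defaults recover their deltas", {
  null_cfg <- small_synth_config(
    target_deltas = list(fixed_graphical = 0, cat_none = 0,
                         cat_graphical = 0, pooled_graphical_text = 0))
  gen <- generate_acceptability(null_cfg, seed = 10)
  expect_true(all(gen$shifts == 0))
  rec <- gen$records
  x <- rec$total[rec$condition != "fixed_none"]
  y <- rec$total[rec$condition == "fixed_none"]
  res <- cliffs_delta(x, y)
  se <- (res$ci_high - res$ci_low) / (2 * stats::qnorm(0.975))
  expect_lt(abs(res$delta), 3 * se)

  # full-size generation recovers the pooled target within sampling error
  cfg <- synth_config()
  rec2 <- generate_acceptability(cfg, seed = 11)$records
  x2 <- rec2$total[rec2$condition %in% c("fixed_graphical_text",
                                         "cat_graphical_text")]
  y2 <- rec2$total[rec2$condition %in% c("fixed_none", "cat_none")]
  res2 <- cliffs_delta(x2, y2)
  se2 <- (res2$ci_high - res2$ci_low) / (2 * stats::qnorm(0.975))
  expect_lt(abs(res2$delta - 0.22), 3 * se2)
})

test_that("respondent allocation matches the configured condition profile", {
  sizes <- synth_config()$condition_sizes
  alloc <- catqol:::proportional_allocation(sizes, 1454L)
  expect_equal(sum(alloc), 1454L)
  expect_true(all(abs(alloc - sizes * 1454 / sum(sizes)) < 1))
  expect_error(synth_config(n_respondents = 100), "at most")
})
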