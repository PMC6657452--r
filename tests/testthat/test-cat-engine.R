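norms4 <- function(domains = "d") {
  stats::setNames(rep(list(list(mean = 0, sd = 1)), length(domains)), domains)
}

test_that("item selection maximizes information at the provisional estimate", {
  bank <- item_bank(list(pcm_item("near", "d", 0), pcm_item("far", "d", 3)))
  expect_equal(select_next_item(bank, character(), 0, "d")$item_id, "near")
  expect_equal(select_next_item(bank, "near", 0, "d")$item_id, "far")
  expect_null(select_next_item(bank, c("near", "far"), 0, "d"))

  set.seed(21)
  bank10 <- item_bank(lapply(1:10, function(i) {
    pcm_item(sprintf("i%02d", i), "d", sort(runif(3, -3, 3)))
  }))
  for (th in c(-1, 0, 1)) {
    info <- vapply(bank10$items, pcm_item_information, numeric(1), theta = th)
    expect_equal(select_next_item(bank10, character(), th, "d")$item_id,
                 names(which.max(info)))
  }
})

test_that("the administration loop honours all three stopping conditions", {
  set.seed(22)
  bank <- item_bank(lapply(1:6, function(i) {
    pcm_item(paste0("i", i), "d", sort(runif(4, -1, 1)))
  }))
  responder <- pcm_responder(0.3)

  loose <- run_cat(bank, responder, cat_config(se_stop = 1e6, norms = norms4()), "d")
  expect_equal(nrow(loose$administered), 2)  # min_items, rule fires at once
  expect_equal(loose$stopped_reason, "se_reached")

  strict <- run_cat(bank, responder, cat_config(se_stop = 1e-6), "d")
  expect_equal(nrow(strict$administered), 6)
  expect_equal(strict$stopped_reason, "bank_exhausted")

  capped <- run_cat(bank, responder,
                    cat_config(se_stop = 1e-6, max_items_per_domain = 3), "d")
  expect_equal(nrow(capped$administered), 3)
  expect_equal(capped$stopped_reason, "max_items")

  expect_equal(length(loose$trajectory), nrow(loose$administered))
  expect_error(run_cat(bank, function(item) 99L, cat_config(), "d"),
               "invalid category")
  expect_error(run_cat(bank, responder, cat_config(), "nope"), "no items")
})

test_that("each session's stopping reason matches exactly one condition", {
  set.seed(23)
  spec <- list(domains = "d", n_items_per_domain = 12L, n_steps = 4L,
               center_range = c(-2, 2), step_spread = 0.25,
               threshold_jitter_sd = 0.15)
  bank <- generate_bank(spec, seed = 3)
  cfg <- cat_config(se_stop = 0.45, max_items_per_domain = 8)
  for (i in 1:50) {
    ses <- run_cat(bank, pcm_responder(rnorm(1)), cfg, "d")
    n <- nrow(ses$administered)
    se <- ses$final$se
    switch(ses$stopped_reason,
      se_reached = {
        expect_lt(se, 0.45)
        expect_gte(n, cfg$min_items_per_domain)
      },
      max_items = {
        expect_equal(n, 8)
        expect_gte(se, 0.45)
      },
      bank_exhausted = {
        expect_equal(n, 12)
        expect_gte(se, 0.45)
      })
  }
})

test_that("mean SE declines as items accumulate across simulated sessions", {
  set.seed(24)
  spec <- list(domains = "d", n_items_per_domain = 10L, n_steps = 4L,
               center_range = c(-2, 2), step_spread = 0.25,
               threshold_jitter_sd = 0.15)
  bank <- generate_bank(spec, seed = 4)
  cfg <- cat_config(se_stop = 1e-6)  # run every session to exhaustion
  ses <- lapply(1:300, function(i) run_cat(bank, pcm_responder(rnorm(1)),
                                           cfg, "d"))
  se_mat <- t(vapply(ses, function(s) {
    vapply(s$trajectory, `[[`, numeric(1), "se")
  }, numeric(10)))
  mean_se <- colMeans(se_mat)
  expect_true(all(diff(mean_se) <= 0.01))
  expect_lt(mean_se[10], mean_se[2])
})

test_that("adaptive estimates track the full-bank estimates", {
  spec <- list(domains = "d", n_items_per_domain = 25L, n_steps = 4L,
               center_range = c(-2, 2), step_spread = 0.25,
               threshold_jitter_sd = 0.15)
  bank <- generate_bank(spec, seed = 5)
  gen <- generate_respondents(bank, 150, seed = 6)
  cfg <- cat_config(se_stop = 0.45)
  ids <- names(bank$items)
  theta_cat <- numeric(150)
  theta_full <- numeric(150)
  n_items <- numeric(150)
  for (r in 1:150) {
    responder <- function(item) gen$responses[r, item$item_id]
    ses <- run_cat(bank, responder, cfg, "d")
    theta_cat[r] <- ses$final$theta
    n_items[r] <- nrow(ses$administered)
    full <- lapply(ids, function(id) list(item = bank$items[[id]],
                                          category = gen$responses[r, id]))
    theta_full[r] <- estimate_theta_mle(full)$theta
  }
  expect_gt(cor(theta_cat, theta_full), 0.9)
  expect_lt(mean(n_items), 25)
})

test_that("trait estimates map to the 0-100 reporting scale", {
  cfg <- cat_config(norms = list(d = list(mean = 0.5, sd = 2)))
  mk <- function(th) list(theta = th)
  expect_equal(theta_to_domain_score(mk(0.5), cfg, "d")$score_0_100, 50)
  expect_equal(theta_to_domain_score(mk(0.5 + 6), cfg, "d")$score_0_100, 100)
  expect_equal(theta_to_domain_score(mk(0.5 - 2), cfg, "d")$score_0_100,
               50 - 100 / 6, tolerance = 1e-12)
  expect_equal(theta_to_domain_score(mk(-100), cfg, "d")$score_0_100, 0)
  expect_error(theta_to_domain_score(mk(0), cfg, "other"), "norm")
})
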