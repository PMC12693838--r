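test_that("daily averaging reduces repeated administrations to one value", {
  long <- data.frame(
    person_id = "p1",
    day_index = c(1, 1, 1, 1, 2, 3),
    variable = "stress",
    value = c(2, 4, 4, 6, 5, NA))
  out <- daily_average(long)
  expect_equal(out$value[out$day_index == 1], 4)
  expect_equal(out$n_items[out$day_index == 1], 4L)
  expect_equal(out$value[out$day_index == 2], 5)    # single administration
  expect_false(3 %in% out$day_index)                # empty day stays missing
})

test_that("lag alignment pairs health day t with HRV of the following night", {
  panel <- data.frame(person_id = "p1", day_index = 1:5,
                      stress = c(10, 20, 30, 40, 50),
                      rmssd = c(61, 62, 63, 64, 65))
  out <- align_lag(panel, "stress", "rmssd", "health_day_to_next_night")
  expect_equal(nrow(out), 4)                        # last day has no next night
  expect_equal(out$rmssd[out$day_index == 3], 64)   # day 3 -> night 4
  expect_equal(attr(out, "n_dropped"), 1)
  same <- align_lag(panel, "stress", "rmssd", "same_day")
  expect_equal(same$rmssd[same$day_index == 3], 63)
  expect_error(align_lag(panel, "stress", "rmssd", "weekly"), "arg")
})

test_that("an identical pair correlates perfectly at both levels", {
  sim <- simulate_panel(panel_config(30, 5, variables = "x",
                                     between_corr = matrix(1),
                                     within_corr = matrix(1), seed = 61))
  d <- sim$panel
  d$y <- d$x
  est <- multilevel_corr(d, "x", "y", estimator = "moments")
  expect_equal(est$within$r, 1, tolerance = 1e-12)
  expect_equal(est$between$r, 1, tolerance = 1e-12)
})

test_that("the ML estimator recovers generating correlations at large n", {
  sim <- simulate_panel(panel_config(
    1000, 10, between_corr = matrix(c(1, 0.5, 0.5, 1), 2),
    within_corr = matrix(c(1, -0.2, -0.2, 1), 2), icc = 0.5, seed = 62))
  est <- multilevel_corr(sim$panel, "x", "y")
  expect_lt(abs(est$between$r - 0.5), 3 * est$between$se)
  expect_lt(abs(est$within$r - (-0.2)), 3 * est$within$se)
})

test_that("a purely between-level association does not leak into the within level", {
  sim <- simulate_panel(panel_config(
    2000, 9, between_corr = matrix(c(1, 0.3, 0.3, 1), 2), icc = 0.5,
    seed = 63))
  est <- multilevel_corr(sim$panel, "x", "y")
  expect_lt(abs(est$within$r), 3 * est$within$se)
  expect_lt(abs(est$between$r - 0.3), 0.05)   # parameter-recovery tolerance
})

test_that("a purely within-level association does not leak into the between level", {
  sim <- simulate_panel(panel_config(
    1000, 10, within_corr = matrix(c(1, 0.4, 0.4, 1), 2), icc = 0.5,
    seed = 64))
  est <- multilevel_corr(sim$panel, "x", "y")
  expect_lt(abs(est$between$r), 3 * est$between$se)
  expect_lt(abs(est$within$r - 0.4), 3 * est$within$se)
})

test_that("moments and ML estimators agree with many observations per person", {
  sim <- simulate_panel(panel_config(
    300, 25, between_corr = matrix(c(1, 0.4, 0.4, 1), 2),
    within_corr = matrix(c(1, 0.15, 0.15, 1), 2), icc = 0.6, seed = 65))
  ml <- multilevel_corr(sim$panel, "x", "y", estimator = "ml")
  mo <- multilevel_corr(sim$panel, "x", "y", estimator = "moments")
  expect_lt(abs(ml$within$r - mo$within$r), 0.02)
  expect_lt(abs(ml$between$r - mo$between$r), 0.02)
})

test_that("covariates independent of both variables leave estimates unchanged", {
  sim <- simulate_panel(panel_config(
    400, 8, between_corr = matrix(c(1, 0.4, 0.4, 1), 2), seed = 66))
  raw <- multilevel_corr(sim$panel, "x", "y")
  adj <- multilevel_corr(sim$panel, "x", "y", covariates = c("age", "gender"))
  expect_equal(adj$between$r, raw$between$r, tolerance = 0.03)
  expect_equal(adj$within$r, raw$within$r, tolerance = 1e-3)
  expect_identical(adj$adjusted_for, c("age", "gender"))
})

test_that("adjustment removes a correlation produced entirely by a confounder", {
  sim <- simulate_panel(panel_config(
    600, 6, covariate_effects = list(age = c(1.5, 1.5)), seed = 67))
  raw <- multilevel_corr(sim$panel, "x", "y")
  adj <- multilevel_corr(sim$panel, "x", "y", covariates = "age")
  expect_gt(raw$between$r, 0.4)              # both person means track age
  expect_lt(abs(adj$between$r), 3 * adj$between$se)
})

test_that("constant covariates are dropped with a warning", {
  sim <- simulate_panel(panel_config(50, 4, seed = 68))
  sim$panel$site <- 1
  expect_warning(est <- multilevel_corr(sim$panel, "x", "y",
                                        covariates = "site"),
                 "constant")
  expect_length(est$adjusted_for, 0)
})

test_that("between-level estimation requires at least three persons", {
  sim <- simulate_panel(panel_config(2, 10, seed = 69))
  est <- multilevel_corr(sim$panel, "x", "y")
  expect_true(is.na(est$between$r))
  expect_match(est$between$flag, "fewer than 3 persons")
  expect_false(is.na(est$within$r))
})

test_that("effect-size labels use the conventional inclusive thresholds", {
  expect_equal(label_effect(-0.32), "medium")
  expect_equal(label_effect(0.10), "small")
  expect_equal(label_effect(0), "below_small")
  expect_equal(label_effect(c(0.5, -0.09, 0.3)),
               c("large", "below_small", "medium"))
  expect_error(label_effect(1.2))
})

test_that("the correlation report is tidy across mixed estimate types", {
  sim <- simulate_panel(panel_config(200, 6, variables = c("x", "y", "d"),
                                     binary_specs = list(d = 0.4), seed = 70))
  per <- sim$panel[!duplicated(sim$panel$person_id), ]
  pm <- tapply(sim$panel$x, sim$panel$person_id, mean)
  est1 <- multilevel_corr(sim$panel, "x", "y")
  est2 <- biserial_corr(as.numeric(pm), per$d)
  rep_tab <- correlation_report(list(est1, est2))
  expect_equal(nrow(rep_tab), 3)             # within+between, biserial between
  expect_setequal(unique(rep_tab$type), c("pearson", "biserial"))
  empty <- correlation_report(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("r", "p", "level") %in% names(empty)))
})
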