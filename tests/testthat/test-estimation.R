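test_that("null PS model concentrates at the exposure prevalence", {
  co <- make_cohort(40, exposure = rep(c(1L, 0L, 0L, 0L), 10))
  ps <- fit_ps(co, character())
  expect_equal(unique(round(ps$ps, 10)), 0.25)
})

test_that("duplicated covariate columns are aliased without changing the fit", {
  sim <- small_sim(1, n = 300)
  cov <- build_covariate_matrix(sim$dimensions, sim$cohort, n_top = 20)
  sel <- colnames(cov)[1:5]
  dup <- cbind(unclass(cov)[, sel], copy = unclass(cov)[, sel[1]])
  expect_message(ps2 <- fit_ps(sim$cohort, "age", dup), "collinear")
  ps1 <- fit_ps(sim$cohort, "age", unclass(cov)[, sel])
  expect_equal(ps2$ps, ps1$ps, tolerance = 1e-10)
  expect_equal(ps2$dropped, "copy")
})

test_that("adding informative HDPS covariates raises the c-statistic", {
  sim <- small_sim(2, n = 800)
  cov <- build_covariate_matrix(sim$dimensions, sim$cohort, n_top = 50)
  pre <- fit_ps(sim$cohort, attr(sim$cohort, "predefined"))
  full <- fit_ps(sim$cohort, attr(sim$cohort, "predefined"), cov)
  expect_gte(full$c_statistic, pre$c_statistic)
})

test_that("IPTW weights follow the inverse-probability definitions", {
  expect_equal(iptw_weights(rep(0.5, 4), c(1L, 0L, 1L, 0L)), rep(2, 4))
  expect_equal(iptw_weights(0.25, 1L), 4)
  expect_equal(iptw_weights(0.25, 0L), 1 / 0.75)
  # stabilized weights average ~1 within each group
  set.seed(9)
  ps <- runif(400, 0.2, 0.8)
  e <- rbinom(400, 1, ps)
  w <- iptw_weights(ps, e, stabilized = TRUE)
  expect_equal(mean(w[e == 1]), 1, tolerance = 0.1)
  expect_equal(mean(w[e == 0]), 1, tolerance = 0.1)
})

test_that("weight rescaling behaves as the partial likelihood dictates", {
  sim <- small_sim(3, n = 500)
  ps <- fit_ps(sim$cohort, attr(sim$cohort, "predefined"))
  w_u <- iptw_weights(ps, sim$cohort$exposure, stabilized = FALSE)
  hr_u <- fit_weighted_cox(sim$cohort, w_u)$log_hr
  # a global rescale leaves the estimate exactly unchanged
  hr_scaled <- fit_weighted_cox(sim$cohort, 3.7 * w_u)$log_hr
  expect_equal(hr_scaled, hr_u, tolerance = 1e-10)
  # stabilization rescales within groups: estimates agree closely but not
  # bitwise (risk sets mix the groups)
  w_s <- iptw_weights(ps, sim$cohort$exposure, stabilized = TRUE)
  hr_s <- fit_weighted_cox(sim$cohort, w_s)$log_hr
  expect_equal(hr_u, hr_s, tolerance = 0.02)
})

test_that("trimming removes the expected tails and refuses to empty a group", {
  sim <- small_sim(4, n = 1000)
  ps <- fit_ps(sim$cohort, attr(sim$cohort, "predefined"))
  wa <- weighted_analysis(ps, sim$cohort)
  expect_identical(trim_ps(wa, 0, 100), wa)  # identity
  suppressMessages(tr <- trim_ps(wa, 1, 99))
  expect_gt(tr$n_trimmed, 0)
  expect_lt(tr$n_trimmed, 40)  # ~2% of 1000
  expect_equal(tr$n_trimmed + sum(tr$keep), nrow(sim$cohort))
  expect_error(trim_ps(wa, 50, 40), "lower_pct")

  # degenerate all-equal scores: nothing removed
  co <- make_cohort(40, exposure = rep(c(1L, 0L), 20))
  wa0 <- weighted_analysis(fit_ps(co, character()), co)
  suppressMessages(tr0 <- trim_ps(wa0, 1, 99))
  expect_equal(tr0$n_trimmed, 0L)
})

test_that("unit weights reproduce the unweighted Cox fit", {
  sim <- small_sim(5, n = 400)
  eff <- fit_weighted_cox(sim$cohort)
  ref <- survival::coxph(survival::Surv(followup_time, event) ~ exposure,
                         data = as.data.frame(sim$cohort), ties = "efron")
  expect_equal(eff$log_hr, unname(coef(ref)), tolerance = 1e-10)
})

test_that("weighted Cox refuses data without events", {
  co <- make_cohort(10, event = rep(0L, 10))
  expect_error(fit_weighted_cox(co), "no outcome events")
})

test_that("compute_clr reproduces its arithmetic and invariances", {
  expect_equal(round(compute_clr(0.78, 1.28), 2), 1.64)
  expect_equal(compute_clr(1.00, 1.35), 1.35)
  expect_equal(compute_clr(0.9, 0.9), 1)
  # scale invariance
  expect_equal(compute_clr(3 * 0.7, 3 * 1.4), compute_clr(0.7, 1.4))
  expect_error(compute_clr(-1, 2), "positive")
  expect_error(compute_clr(2, 1), ">=")
})
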