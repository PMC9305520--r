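test_that("asd_binary matches hand arithmetic, is symmetric, handles degeneracy", {
  expect_equal(asd_binary(0.3, 0.3), 0)
  expect_equal(asd_binary(0.3, 0.1), 100 * 0.2 / sqrt(0.15))
  expect_equal(asd_binary(1, 1), 0)
  expect_equal(asd_binary(0, 0), 0)
  p <- runif(20); q <- runif(20)
  expect_equal(asd_binary(p, q), asd_binary(q, p))
  expect_error(asd_binary(1.2, 0.5), "\\[0, 1\\]")
})

test_that("balance table: unit weights reproduce the unweighted column", {
  sim <- small_sim(6, n = 300)
  cov <- build_covariate_matrix(sim$dimensions, sim$cohort, n_top = 20)
  b <- balance_table(cov, sim$cohort,
                     weight_sets = list(unit = rep(1, nrow(sim$cohort))),
                     predefined = c("age", "sex"))
  expect_equal(b$asd_unit, b$asd_unweighted, tolerance = 1e-12)
  expect_equal(nrow(b), ncol(cov) + 2L)
})

test_that("balance table flags weight sets with non-positive group totals", {
  co <- make_cohort(6)
  x <- matrix(rep(c(0L, 1L), 3), ncol = 1,
              dimnames = list(co$patient_id, "c1"))
  w <- ifelse(co$exposure == 1, 0, 1)
  expect_error(balance_table(x, co, weight_sets = list(bad = w)),
               "non-positive")
})

test_that("a perfectly balanced covariate has zero ASD in all columns", {
  co <- make_cohort(8, exposure = rep(c(1L, 0L), 4))
  x <- matrix(rep(c(1L, 1L, 0L, 0L), 2), ncol = 1,
              dimnames = list(co$patient_id, "bal"))
  b <- balance_table(x, co, weight_sets = list(w = rep(2, 8)))
  expect_equal(b$asd_unweighted, 0)
  expect_equal(b$asd_w, 0)
})

test_that("importance weights follow ((N+1) - rank)/N", {
  expect_equal(importance_weight(1, 250), 1)
  expect_equal(importance_weight(250, 250), 1 / 250)
  expect_equal(importance_weight(126, 250), 0.5)
  w <- importance_weight(1:100, 100)
  expect_true(all(diff(w) < 0))  # strictly decreasing
  expect_error(importance_weight(0, 10), "1..N")
  expect_error(importance_weight(11, 10), "1..N")
})

test_that("mean_asd averages plainly or by importance weight", {
  expect_equal(mean_asd(7.5), 7.5)
  expect_equal(mean_asd(c(4, 2), c(1.0, 0.5)), 5 / 1.5)
  # rank -> infinity limit: weight -> 0 leaves only the first covariate
  expect_equal(mean_asd(c(10, 0), c(1, 1e-12)), 10, tolerance = 1e-9)
  expect_error(mean_asd(numeric(0)), "empty")
})

test_that("overlap coefficient is 1 for identical and 0 for disjoint scores", {
  mk <- function(ps, label) {
    structure(list(label = label, ps = ps, covariates = character(),
                   dropped = character(), converged = TRUE,
                   c_statistic = NA_real_, coefficients = numeric()),
              class = "hdps_ps")
  }
  e <- rep(c(1L, 0L), each = 50)
  same <- mk(rep(seq(0.1, 0.9, length.out = 50), 2), "same")
  ov1 <- ps_overlap_summary(list(m = same), exposure = e)
  expect_equal(unname(ov1$overlap["m"]), 1, tolerance = 1e-12)

  apart <- mk(c(seq(0.7, 0.9, length.out = 50),
                seq(0.1, 0.3, length.out = 50)), "apart")
  ov0 <- ps_overlap_summary(list(m = apart), exposure = e)
  expect_equal(unname(ov0$overlap["m"]), 0)
})

test_that("richer PS models reduce overlap on confounded synthetic data", {
  sim <- generate_study(sim_config(n_patients = 1500,
                                   codes_per_dimension = 20,
                                   n_iv_codes = 3, n_noise_codes = 5,
                                   seed = 8))
  fit <- hdps(sim$cohort, sim$dimensions, n_top = 60, k = 40)
  expect_lt(fit$overlap$overlap[["predefined + HDPS"]],
            fit$overlap$overlap[["predefined"]])
})

test_that("prevalence scatter flags covariates outside the PR band", {
  pri <- make_prioritised(c("on_line", "pr3", "protective"),
                          rr_ce = c(1, 3, 0.3), rr_cd = c(1, 1, 1),
                          pc1 = c(0.2, 0.3, 0.06), pc0 = c(0.2, 0.1, 0.2))
  sc <- prevalence_scatter(pri)
  expect_equal(sc$flagged, c(FALSE, TRUE, TRUE))
  expect_equal(sc$pr[2], 3)
})

test_that("bias distribution is non-increasing with dimension counts", {
  pri <- rank_covariates(make_prioritised(
    paste0("c", 1:6), rr_ce = rep(1, 6), rr_cd = c(3, 1.2, 2, 1, 1.5, 5),
    dimension = rep(c("clinical", "therapy"), 3)), "bross")
  bd <- bias_distribution(pri)
  expect_true(all(diff(bd$values$abs_log_bias) <= 0))
  expect_equal(sum(bd$dimension_counts), 6)
  # all-null biases: flat zero line
  flat <- bias_distribution(rank_covariates(
    make_prioritised(c("a", "b"), rr_ce = c(1, 1), rr_cd = c(1, 1)),
    "bross"))
  expect_equal(flat$values$abs_log_bias, c(0, 0))
})

test_that("association scatter reports |rr - 1| strengths", {
  pri <- make_prioritised(c("null", "iv", "prot"),
                          rr_ce = c(1, 2, 0.5), rr_cd = c(1, 1.05, 1))
  a <- association_scatter(pri)
  expect_equal(a$strength_exposure, c(0, 1, 0.5))
  expect_equal(a$strength_outcome, c(0, 0.05, 0))
})

test_that("near-IV flagging applies the |log rr| thresholds", {
  pri <- make_prioritised(c("clear_iv", "null_ce", "mid"),
                          rr_ce = c(exp(2), 1, exp(1.3)),
                          rr_cd = c(1, 1, 1.1))
  expect_setequal(flag_near_ivs(pri, near_iv_rule(1.5, 0.5)), "clear_iv")
  expect_setequal(flag_near_ivs(pri, near_iv_rule(1.1, 0.5)),
                  c("clear_iv", "mid"))
  # strong outcome association blocks the flag
  pri2 <- make_prioritised("confounder", rr_ce = exp(2), rr_cd = exp(0.8))
  expect_length(flag_near_ivs(pri2, near_iv_rule(1.1, 0.5)), 0)
})

test_that("the laxer exposure threshold flags a superset", {
  set.seed(11)
  for (i in 1:20) {
    pri <- make_prioritised(paste0("c", 1:30),
                            rr_ce = exp(rnorm(30, 0, 1.2)),
                            rr_cd = exp(rnorm(30, 0, 0.5)))
    f15 <- flag_near_ivs(pri, near_iv_rule(1.5, 0.5))
    f11 <- flag_near_ivs(pri, near_iv_rule(1.1, 0.5))
    expect_true(all(f15 %in% f11))
  }
})

test_that("concept summary conserves counts and routes unmapped codes", {
  pri <- make_prioritised(c("I21", "I22", "K50"),
                          rr_ce = c(1, 1, 1), rr_cd = c(1, 1, 1))
  h <- as_code_hierarchy(c("I21", "I22"), c("IX", "IX"))
  cs <- concept_summary(pri, h)
  expect_equal(sum(cs$n), 3)
  expect_equal(cs$n[cs$chapter == "IX"], 2)
  expect_equal(cs$n[cs$chapter == "unmapped"], 1)
  # empty selection
  expect_equal(nrow(concept_summary(pri, h, names = character())), 0)
})
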