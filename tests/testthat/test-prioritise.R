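test_that("bross_bias matches direct arithmetic and its identities", {
  expect_equal(bross_bias(0.4, 0.2, 2), 1.4 / 1.2)
  expect_equal(bross_bias(0.3, 0.3, 7), 1)     # equal prevalences
  expect_equal(bross_bias(0.6, 0.1, 1), 1)     # null outcome association
  # invariance under rr -> 1/rr via the max rule
  expect_equal(bross_bias(0.35, 0.15, 2.5), bross_bias(0.35, 0.15, 0.4))
  expect_error(bross_bias(1.2, 0.5, 2), "proportions")
  expect_error(bross_bias(0.5, 0.5, -1), "rr_cd")
})

test_that("bross_bias is monotone in prevalences for rr > 1", {
  grid <- seq(0.05, 0.95, by = 0.15)
  for (rr in c(1.5, 3, 10)) {
    for (p0 in grid) {
      vals <- bross_bias(grid, p0, rr)
      expect_true(all(diff(vals) > 0))  # increasing in pc1
    }
    for (p1 in grid) {
      vals <- bross_bias(p1, grid, rr)
      expect_true(all(diff(vals) < 0))  # decreasing in pc0
    }
  }
})

test_that("univariate associations reproduce 2x2 hand computations", {
  # events: 4/10 when C=1, 2/10 when C=0 -> rr_cd = 2; pc1 = pc0 -> rr_ce = 1
  co <- make_cohort(20,
                    exposure = rep(c(1L, 0L), 10),
                    event = c(rep(1L, 4), rep(0L, 6), rep(1L, 2), rep(0L, 8)))
  x <- matrix(c(rep(1L, 10), rep(0L, 10)), ncol = 1,
              dimnames = list(co$patient_id, "cov"))
  pri <- univariate_associations(x, co)
  expect_equal(pri$rr_cd, 2)
  expect_equal(pri$pc1, 0.5)
  expect_equal(pri$pc0, 0.5)
  expect_equal(pri$rr_ce, 1)
})

test_that("zero cells are continuity-corrected to finite ratios", {
  co <- make_cohort(10, exposure = rep(c(1L, 0L), 5),
                    event = c(rep(1L, 5), rep(0L, 5)))
  x <- matrix(co$exposure, ncol = 1,
              dimnames = list(co$patient_id, "same_as_exposure"))
  pri <- univariate_associations(x, co)
  expect_true(is.finite(pri$rr_ce) && pri$rr_ce > 0)
  expect_true(is.finite(pri$rr_cd) && pri$rr_cd > 0)
})

test_that("constant covariates are excluded with a message", {
  co <- make_cohort(10)
  x <- cbind(allzero = rep(0L, 10), ok = rep(c(0L, 1L), 5))
  rownames(x) <- co$patient_id
  expect_message(pri <- univariate_associations(x, co), "allzero")
  expect_equal(pri$name, "ok")
})

test_that("associations match an independent brute-force tabulation", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(20:50, 1)
    co <- make_cohort(n,
                      exposure = c(1L, 0L, sample(0:1, n - 2, replace = TRUE)),
                      event = sample(0:1, n, replace = TRUE))
    k <- sample(2:10, 1)
    x <- matrix(stats::rbinom(n * k, 1L, runif(1, 0.2, 0.8)), ncol = k,
                dimnames = list(co$patient_id, paste0("c", seq_len(k))))
    pri <- suppressMessages(univariate_associations(x, co))
    for (i in seq_len(nrow(pri))) {
      oracle <- brute_force_assoc(x[, pri$name[i]], co$exposure, co$event)
      expect_identical(pri$pc1[i], oracle$pc1)
      expect_identical(pri$pc0[i], oracle$pc0)
      expect_identical(pri$rr_ce[i], oracle$rr_ce)
      expect_identical(pri$rr_cd[i], oracle$rr_cd)
      expect_identical(pri$bias_m[i],
                       bross_bias(oracle$pc1, oracle$pc0, oracle$rr_cd))
    }
  }
})

test_that("ranking orders by score with lexicographic tie-break", {
  pri <- make_prioritised(c("b", "a", "c"),
                          rr_ce = c(1, 1, 1), rr_cd = c(1, 1, 1),
                          pc1 = c(0.40, 0.30, 0.35), pc0 = rep(0.2, 3))
  pri$rr_cd <- c(2, 2, 2)
  pri$bias_m <- bross_bias(pri$pc1, pri$pc0, pri$rr_cd)
  pri$abs_log_bias <- abs(log(pri$bias_m))
  r <- rank_covariates(pri, "bross")
  expect_equal(r$name, c("b", "c", "a"))
  expect_equal(r$rank, 1:3)

  # all tied: name order, ranks still a permutation
  tied <- make_prioritised(c("z", "m", "a"), rr_ce = 1, rr_cd = 1)
  rt <- rank_covariates(tied, "bross")
  expect_equal(rt$name, c("a", "m", "z"))
  expect_equal(sort(rt$rank), 1:3)
})

test_that("exposure-only ranking uses |log rr_ce|", {
  pri <- make_prioritised(c("x4", "x02", "x1"),
                          rr_ce = c(4.0, 0.2, 1.0), rr_cd = c(1, 1, 1))
  r <- rank_covariates(pri, "exposure_only")
  expect_equal(r$name, c("x02", "x4", "x1"))  # |log|: 1.61 > 1.39 > 0
  expect_error(rank_covariates(pri, "nonsense"))
})

test_that("select_top_k handles k = 0, k > N and rank order", {
  pri <- rank_covariates(make_prioritised(c("a", "b", "c"),
                                          rr_ce = c(3, 2, 1),
                                          rr_cd = c(1, 1, 1)),
                         "exposure_only")
  expect_equal(select_top_k(pri, 0), character(0))
  expect_equal(select_top_k(pri, 2), c("a", "b"))
  expect_message(all3 <- select_top_k(pri, 500), "only 3")
  expect_equal(all3, c("a", "b", "c"))
  expect_error(select_top_k(pri, -1), "k must be")
})

test_that("planted confounder proxies rank better than noise codes", {
  prox_ranks <- noise_ranks <- numeric(0)
  for (seed in 1:12) {
    sim <- small_sim(seed, n = 700, codes = 12, iv = 2, noise = 4)
    cov <- build_covariate_matrix(sim$dimensions, sim$cohort, n_top = 50)
    pri <- rank_covariates(
      suppressMessages(univariate_associations(cov, sim$cohort)), "bross")
    roles <- sim$truth$code_roles
    pri$role <- roles$role[match(paste(pri$dimension, pri$code),
                                 paste(roles$dimension, roles$code))]
    prox_ranks <- c(prox_ranks,
                    mean(pri$rank[pri$role == "confounder_proxy"]))
    noise_ranks <- c(noise_ranks, mean(pri$rank[pri$role == "noise"]))
  }
  p <- stats::wilcox.test(prox_ranks, noise_ranks,
                          alternative = "less")$p.value
  expect_lt(p, 0.01)
})

test_that("with proxy_loading = 0 proxies are exchangeable with noise", {
  sim <- generate_study(sim_config(n_patients = 800,
                                   codes_per_dimension = 12,
                                   n_iv_codes = 2, n_noise_codes = 5,
                                   proxy_loading = 0, seed = 3))
  cov <- build_covariate_matrix(sim$dimensions, sim$cohort, n_top = 50)
  pri <- rank_covariates(
    suppressMessages(univariate_associations(cov, sim$cohort)), "bross")
  roles <- sim$truth$code_roles
  pri$role <- roles$role[match(paste(pri$dimension, pri$code),
                               paste(roles$dimension, roles$code))]
  p <- stats::wilcox.test(pri$rank[pri$role == "confounder_proxy"],
                          pri$rank[pri$role == "noise"])$p.value
  expect_gt(p, 0.05)
})
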