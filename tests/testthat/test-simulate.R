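test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(proxy_loading = -1), "proxy_loading")
  expect_error(sim_config(admin_censor_time = 0), "admin_censor_time")
  expect_error(sim_config(codes_per_dimension = 10, n_iv_codes = 5,
                          n_noise_codes = 5), "exceed")
  expect_s3_class(sim_config(), "hdps_sim_config")
})

test_that("identical seeds give identical studies; different seeds differ", {
  a <- small_sim(5)
  b <- small_sim(5)
  c <- small_sim(6)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(lapply(a$dimensions, as.data.frame),
                   lapply(b$dimensions, as.data.frame))
  expect_false(identical(as.data.frame(a$cohort), as.data.frame(c$cohort)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(small_sim(1, n = 100))
  expect_identical(.Random.seed, before)
})

test_that("truth record accounts for every code exactly once", {
  sim <- small_sim(2, codes = 12, iv = 2, noise = 3)
  ts <- truth_summary(sim$truth)
  expect_equal(sum(ts$n_codes), 3 * 12)
  expect_equal(ts$n_codes[ts$role == "iv_like"], 3 * 2)
  expect_equal(ts$n_codes[ts$role == "noise"], 3 * 3)
  expect_equal(attr(ts, "true_log_hr"), 0)
  expect_error(hdps:::new_truth(0, NULL, NULL,
                                data.frame(), 1), "non-empty")
})

test_that("code prevalence rises with the base rate parameter", {
  sim <- generate_study(sim_config(n_patients = 2000,
                                   codes_per_dimension = 30,
                                   n_iv_codes = 1, n_noise_codes = 14,
                                   seed = 4))
  roles <- sim$truth$code_roles
  noise <- roles[roles$role == "noise", ]  # rate is the only driver
  d <- sim$dimensions[[1]]
  noise1 <- noise[noise$dimension == attr(d, "dimension_name"), ]
  prev <- vapply(noise1$code, function(cd) {
    length(unique(d$patient_id[d$code == cd])) / nrow(sim$cohort)
  }, numeric(1))
  expect_gt(stats::cor(noise1$base_rate, prev, method = "spearman"), 0.9)
})

test_that("all generated events fall in the pre-exposure window", {
  sim <- small_sim(7, n = 200)
  for (d in sim$dimensions) {
    r <- restrict_pre_exposure(d, sim$cohort,
                               sim$config$lookback_days)
    expect_equal(nrow(r), nrow(d))
  }
})

test_that("without confounding the crude estimate is unbiased", {
  # empirical mean of the crude log-HR over replicates vs Monte-Carlo SE
  log_hrs <- vapply(1:60, function(s) {
    sim <- generate_study(sim_config(n_patients = 500,
                                     codes_per_dimension = 6,
                                     n_iv_codes = 1, n_noise_codes = 2,
                                     confounding_log_hr = 0,
                                     true_log_hr = 0.3, seed = s))
    fit_weighted_cox(sim$cohort)$log_hr
  }, numeric(1))
  mc_se <- stats::sd(log_hrs) / sqrt(length(log_hrs))
  expect_lt(abs(mean(log_hrs) - 0.3), 3 * mc_se)
})

test_that("a confounded null study shows crude bias that HDPS removes", {
  sim <- generate_study(sim_config(n_patients = 5000,
                                   confounding_log_hr = 0.5,
                                   true_log_hr = 0, seed = 1))
  fit <- hdps(sim$cohort, sim$dimensions, k = 100, diagnostics = FALSE)
  crude <- fit$effects$crude$hazard_ratio
  adj <- fit$effects$hdps$hazard_ratio
  expect_gt(crude, 1)                       # confounding inflates
  expect_lt(abs(log(adj)), abs(log(crude))) # adjustment moves towards null
})

test_that("studies round-trip through the delimited-text writers", {
  sim <- small_sim(9, n = 60, codes = 5, iv = 1, noise = 1)
  dir <- withr::local_tempdir()
  write_study(sim, dir)
  co <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(as.data.frame(co), as.data.frame(sim$cohort))
  for (nm in names(sim$dimensions)) {
    d <- read_dimension(file.path(dir, paste0("dimension_", nm, ".csv")),
                        nm, co)
    expect_equal(as.data.frame(d), as.data.frame(sim$dimensions[[nm]]))
  }
  truth_lines <- readLines(file.path(dir, "truth.txt"))
  expect_true("true_log_hr=0" %in% truth_lines)
})
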