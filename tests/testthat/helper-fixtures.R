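# Hand-built fixtures used across the suite. All tiny, built in code.

make_cohort <- function(n = 8, exposure = rep(c(1L, 0L), length.out = n),
                        event = rep(c(1L, 0L), each = ceiling(n / 2))[1:n],
                        followup = rep(100, n),
                        index_date = as.Date("2020-06-01"),
                        extra = NULL) {
  df <- data.frame(patient_id = sprintf("pt%02d", seq_len(n)),
                   index_date = format(rep(index_date, length.out = n),
                                       "%Y-%m-%d"),
                   exposure = exposure, event = event,
                   followup_time = followup,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  as_cohort(df)
}

make_dimension <- function(cohort, patient, code, days_before = 30,
                           name = "clinical") {
  idx <- cohort$index_date[match(patient, cohort$patient_id)]
  df <- data.frame(patient_id = patient, code = code,
                   date = format(idx - days_before, "%Y-%m-%d"),
                   stringsAsFactors = FALSE)
  as_dimension(df, name, cohort)
}

# unranked prioritised table built directly from association values
make_prioritised <- function(name, rr_ce, rr_cd,
                             pc1 = rep(0.3, length(name)),
                             pc0 = rep(0.2, length(name)),
                             dimension = rep("clinical", length(name))) {
  out <- data.frame(name = name, dimension = dimension, code = name,
                    cutoff = "once", pc1 = pc1, pc0 = pc0,
                    rr_ce = rr_ce, rr_cd = rr_cd,
                    bias_m = bross_bias(pc1, pc0, rr_cd),
                    stringsAsFactors = FALSE)
  out$abs_log_bias <- abs(log(out$bias_m))
  class(out) <- c("hdps_prioritised", "data.frame")
  out
}

# small random study used by several property tests
small_sim <- function(seed, n = 600, codes = 12, iv = 2, noise = 3) {
  generate_study(sim_config(n_patients = n, codes_per_dimension = codes,
                            n_iv_codes = iv, n_noise_codes = noise,
                            seed = seed))
}

# independent brute-force 2x2 tabulation (oracle for univariate_associations)
brute_force_assoc <- function(x, exposure, event) {
  tab <- function(a, b) {
    # a: group indicator (1/0 columns are the two groups), b: positive trait
    cells <- c(sum(b == 1 & a == 1), sum(b == 0 & a == 1),
               sum(b == 1 & a == 0), sum(b == 0 & a == 0))
    if (min(cells) == 0) cells <- cells + 0.1
    p1 <- cells[1] / (cells[1] + cells[2])
    p0 <- cells[3] / (cells[3] + cells[4])
    c(p1 = p1, p0 = p0, rr = p1 / p0)
  }
  ce <- tab(exposure, x)   # prevalence of x within exposure groups
  cd <- tab(x, event)      # risk of event within covariate groups
  list(pc1 = unname(ce["p1"]), pc0 = unname(ce["p0"]),
       rr_ce = unname(ce["rr"]), rr_cd = unname(cd["rr"]))
}
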