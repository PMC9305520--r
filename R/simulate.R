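#' Configuration for the synthetic claims-data simulator
#'
#' Defines a simulated cohort study with coded healthcare event streams
#' whose codes are noisy proxies of latent confounders, plus planted
#' instrument-like codes (associated with exposure only) and pure-noise
#' codes. All downstream stages — feature generation, prioritisation,
#' weighting, diagnostics — can then be validated against known truth.
#'
#' The generative model: per patient, latent confounders `U_j ~ N(0,1)`
#' enter both a logistic exposure model and an exponential survival model
#' (each with coefficient `confounding_log_hr`); an exposure-only latent
#' `V ~ N(0,1)` enters the exposure model only, so codes loading on it are
#' true near-instruments. Per code, per-patient event counts are Poisson
#' with log-rate `log(base) + proxy_loading * Z`, where `Z` is the code's
#' latent (`U_j` for confounder proxies, `V` for instrument-like codes,
#' nothing for noise codes); counts are expanded to dated records uniform
#' within the lookback window before each patient's index date. Follow-up
#' is exponential with log-hazard `true_log_hr * exposure +
#' confounding_log_hr * sum(U)` plus small measured-covariate effects, with
#' administrative censoring at `admin_censor_time`.
#'
#' @param n_patients Cohort size.
#' @param n_dimensions Number of data dimensions (event streams).
#' @param codes_per_dimension Codes per dimension; must exceed
#'   `n_iv_codes + n_noise_codes`.
#' @param n_latent_confounders Number of latent confounders `U_j`.
#' @param proxy_loading Strength linking a latent to its codes' log-rates
#'   (>= 0; 0 makes every code uninformative).
#' @param n_iv_codes Instrument-like codes per dimension.
#' @param n_noise_codes Pure-noise codes per dimension.
#' @param true_log_hr True treatment effect on the log-hazard.
#' @param confounding_log_hr Effect of each latent confounder on both the
#'   exposure log-odds and the log-hazard.
#' @param baseline_hazard Baseline hazard per unit time (days).
#' @param admin_censor_time Administrative censoring time (days).
#' @param lookback_days Length of the pre-exposure window.
#' @param seed Integer seed; identical seeds give identical studies.
#' @return An object of class `hdps_sim_config`.
#' @export
sim_config <- function(n_patients = 5000,
                       n_dimensions = 3,
                       codes_per_dimension = 40,
                       n_latent_confounders = 2,
                       proxy_loading = 1.0,
                       n_iv_codes = 5,
                       n_noise_codes = 10,
                       true_log_hr = 0,
                       confounding_log_hr = 0.33,
                       baseline_hazard = 0.0006,
                       admin_censor_time = 365,
                       lookback_days = 365,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients, n_dimensions = n_dimensions,
              codes_per_dimension = codes_per_dimension,
              n_latent_confounders = n_latent_confounders,
              proxy_loading = proxy_loading, n_iv_codes = n_iv_codes,
              n_noise_codes = n_noise_codes, true_log_hr = true_log_hr,
              confounding_log_hr = confounding_log_hr,
              baseline_hazard = baseline_hazard,
              admin_censor_time = admin_censor_time,
              lookback_days = lookback_days, seed = as.integer(seed))
  counts <- c("n_patients", "n_dimensions", "codes_per_dimension",
              "n_latent_confounders", "lookback_days")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != floor(v)) {
      stop("configuration error: '", nm, "' must be an integer count >= 1",
           call. = FALSE)
    }
  }
  for (nm in c("n_iv_codes", "n_noise_codes")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v != floor(v)) {
      stop("configuration error: '", nm, "' must be an integer count >= 0",
           call. = FALSE)
    }
  }
  if (cfg$proxy_loading < 0) {
    stop("configuration error: proxy_loading must be >= 0", call. = FALSE)
  }
  if (cfg$admin_censor_time <= 0 || cfg$baseline_hazard <= 0) {
    stop("configuration error: baseline_hazard and admin_censor_time must be > 0",
         call. = FALSE)
  }
  if (cfg$codes_per_dimension <= cfg$n_iv_codes + cfg$n_noise_codes) {
    stop("configuration error: codes_per_dimension must exceed n_iv_codes + n_noise_codes",
         call. = FALSE)
  }
  structure(cfg, class = "hdps_sim_config")
}

# fixed internal coefficients (documented in the methods vignette):
# exposure model intercept, instrument strength on the exposure log-odds,
# and small measured-covariate effects on exposure and hazard.
sim_constants <- function() {
  list(alpha0 = -0.4, iv_exposure_coef = 1.0, iv_loading_factor = 2.8,
       age_exp = 0.02, sex_exp = 0.2, smoker_exp = 0.3,
       age_out = 0.01, sex_out = 0.1, smoker_out = 0.3,
       base_rate_range = c(0.05, 0.4), iv_base_rate_range = c(0.03, 0.12))
}

#' Generate a complete synthetic study
#'
#' Draws a cohort, one event table per data dimension, and a truth record
#' holding the generating parameters and the role of every code
#' (`confounder_proxy`, `iv_like`, `noise`). Measured covariates `age`,
#' `sex` and `smoker` are generated with small effects on both exposure and
#' outcome and serve as the pre-defined covariates.
#'
#' @param config An [sim_config()] object.
#' @return An object of class `hdps_sim`: list with `cohort`
#'   (`hdps_cohort`), `dimensions` (named list of `hdps_dimension`),
#'   `truth` (`hdps_truth`) and `config`.
#' @export
generate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "hdps_sim_config"))
  k <- sim_constants()
  n <- config$n_patients
  L <- config$n_latent_confounders
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  patient_id <- sprintf("P%06d", seq_len(n))
  index_date <- as.Date("2019-01-01") + sample.int(365, n, replace = TRUE) - 1L
  age <- round(stats::rnorm(n, 65, 10), 1)
  sex <- stats::rbinom(n, 1L, 0.5)
  smoker <- stats::rbinom(n, 1L, 0.3)

  U <- matrix(stats::rnorm(n * L), nrow = n)
  V <- stats::rnorm(n)
  lin_exp <- k$alpha0 + config$confounding_log_hr * rowSums(U) +
    k$iv_exposure_coef * V +
    k$age_exp * (age - 65) + k$sex_exp * sex + k$smoker_exp * smoker
  exposure <- stats::rbinom(n, 1L, stats::plogis(lin_exp))

  lin_out <- config$true_log_hr * exposure +
    config$confounding_log_hr * rowSums(U) +
    k$age_out * (age - 65) + k$sex_out * sex + k$smoker_out * smoker
  t_event <- stats::rexp(n, rate = config$baseline_hazard * exp(lin_out))
  event <- as.integer(t_event <= config$admin_censor_time)
  followup_time <- pmin(t_event, config$admin_censor_time)

  cohort <- as_cohort(data.frame(
    patient_id = patient_id,
    index_date = format(index_date, "%Y-%m-%d"),
    exposure = exposure, event = event,
    followup_time = followup_time,
    age = age, sex = sex, smoker = smoker,
    stringsAsFactors = FALSE))

  dim_names <- if (config$n_dimensions == 3) {
    c("clinical", "referral", "therapy")
  } else {
    sprintf("dim%02d", seq_len(config$n_dimensions))
  }
  n_proxy <- config$codes_per_dimension - config$n_iv_codes -
    config$n_noise_codes
  roles_per_dim <- c(rep("confounder_proxy", n_proxy),
                     rep("iv_like", config$n_iv_codes),
                     rep("noise", config$n_noise_codes))
  br <- k$base_rate_range

  dims <- list()
  role_rows <- list()
  for (d in seq_along(dim_names)) {
    dn <- dim_names[d]
    codes <- sprintf("%s%03d", toupper(substr(dn, 1L, 3L)),
                     seq_len(config$codes_per_dimension))
    base_rate <- ifelse(
      roles_per_dim == "iv_like",
      exp(stats::runif(length(codes), log(k$iv_base_rate_range[1]),
                       log(k$iv_base_rate_range[2]))),
      exp(stats::runif(length(codes), log(br[1]), log(br[2]))))
    all_counts <- matrix(0L, nrow = n, ncol = length(codes))
    for (j in seq_along(codes)) {
      z <- switch(roles_per_dim[j],
                  confounder_proxy = U[, ((j - 1L) %% L) + 1L],
                  iv_like = V,
                  noise = rep(0, n))
      loading <- config$proxy_loading *
        if (roles_per_dim[j] == "iv_like") k$iv_loading_factor else 1
      lambda <- base_rate[j] * exp(loading * z)
      all_counts[, j] <- stats::rpois(n, lambda)
    }
    tot <- sum(all_counts)
    pid <- rep(rep(patient_id, times = length(codes)), times = all_counts)
    cde <- rep(rep(codes, each = n), times = all_counts)
    idx <- rep(rep(index_date, times = length(codes)), times = all_counts)
    offset <- sample.int(config$lookback_days, tot, replace = TRUE)
    ev <- data.frame(patient_id = pid, code = cde,
                     date = format(idx - offset, "%Y-%m-%d"),
                     stringsAsFactors = FALSE)
    ev <- ev[order(ev$patient_id, ev$code, ev$date), , drop = FALSE]
    dims[[dn]] <- suppressMessages(as_dimension(ev, dn, cohort))
    role_rows[[dn]] <- data.frame(dimension = dn, code = codes,
                                  role = roles_per_dim,
                                  base_rate = base_rate,
                                  stringsAsFactors = FALSE)
  }
  truth <- new_truth(
    true_log_hr = config$true_log_hr,
    latent = U, iv_latent = V,
    code_roles = do.call(rbind, c(role_rows, make.row.names = FALSE)),
    crude_expected_direction = sign(config$confounding_log_hr))

  structure(list(cohort = cohort, dimensions = dims, truth = truth,
                 config = config),
            class = "hdps_sim")
}

new_truth <- function(true_log_hr, latent, iv_latent, code_roles,
                      crude_expected_direction) {
  if (is.null(code_roles) || nrow(code_roles) == 0L) {
    stop("truth record requires a non-empty code-role map", call. = FALSE)
  }
  if (!all(code_roles$role %in% c("confounder_proxy", "iv_like", "noise"))) {
    stop("unknown code role in truth record", call. = FALSE)
  }
  structure(list(true_log_hr = true_log_hr, latent = latent,
                 iv_latent = iv_latent, code_roles = code_roles,
                 crude_expected_direction = crude_expected_direction),
            class = "hdps_truth")
}

#' Summarise a truth record
#'
#' @param truth An `hdps_truth` from [generate_study()].
#' @return Data frame of code-role counts (summing to the total number of
#'   generated codes), with the effect parameters as attributes.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "hdps_truth"))
  tab <- as.data.frame(table(role = truth$code_roles$role),
                       stringsAsFactors = FALSE)
  names(tab) <- c("role", "n_codes")
  attr(tab, "true_log_hr") <- truth$true_log_hr
  attr(tab, "crude_expected_direction") <- truth$crude_expected_direction
  tab
}

#' @export
print.hdps_sim <- function(x, ...) {
  cat(sprintf("Synthetic HDPS study: %d patients, %d dimensions, seed %d\n",
              nrow(x$cohort), length(x$dimensions), x$config$seed))
  print(truth_summary(x$truth))
  invisible(x)
}

#' Write a synthetic study to a directory as delimited text
#'
#' Writes `cohort.csv`, one `dimension_<name>.csv` per dimension and a
#' flat key-value `truth.txt` (parameters and code roles).
#'
#' @param sim An `hdps_sim` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "hdps_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "cohort.csv"))
  for (nm in names(sim$dimensions)) {
    write_dimension(sim$dimensions[[nm]],
                    file.path(dir, paste0("dimension_", nm, ".csv")))
  }
  tr <- sim$truth
  lines <- c(sprintf("true_log_hr=%g", tr$true_log_hr),
             sprintf("crude_expected_direction=%g",
                     tr$crude_expected_direction),
             sprintf("role_%s_%s=%s", tr$code_roles$dimension,
                     tr$code_roles$code, tr$code_roles$role))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
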