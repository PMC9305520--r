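#' Fit the propensity score by multivariable logistic regression
#'
#' Regresses the binary exposure on the pre-defined covariates plus the
#' selected HDPS covariates by maximum-likelihood logistic regression.
#' Perfectly collinear columns are aliased by the QR decomposition and
#' dropped with a message; they change neither the fitted scores nor the
#' weights. Fitted scores at machine 0/1 indicate separation (a positivity
#' failure) and raise an error suggesting trimming or a smaller covariate
#' set.
#'
#' @param cohort The cohort; its extra columns are the pre-defined
#'   covariates.
#' @param predefined Character vector of pre-defined covariate names
#'   (columns of `cohort`); may be empty.
#' @param covariates An `hdps_covmatrix` aligned to the cohort, or `NULL`.
#' @param hdps_names Names of HDPS covariates (columns of `covariates`) to
#'   include; default all.
#' @param label Model label carried into downstream summaries.
#' @return An object of class `hdps_ps`: list with `label`, `covariates`
#'   (names used, post aliasing), `dropped` (aliased names), `ps` (fitted
#'   scores), `converged`, `c_statistic`, `coefficients`.
#' @export
fit_ps <- function(cohort, predefined = character(), covariates = NULL,
                   hdps_names = NULL, label = "ps") {
  stopifnot(inherits(cohort, "hdps_cohort"))
  bad <- setdiff(predefined, names(cohort))
  if (length(bad) > 0L) {
    stop("pre-defined covariate(s) not in cohort: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X <- NULL
  if (length(predefined) > 0L) {
    X <- as.matrix(as.data.frame(cohort)[predefined])
  }
  if (!is.null(covariates)) {
    mat <- unclass(covariates)
    if (is.null(hdps_names)) hdps_names <- colnames(mat)
    miss <- setdiff(hdps_names, colnames(mat))
    if (length(miss) > 0L) {
      stop("HDPS covariate(s) not in matrix: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(mat) != nrow(cohort)) {
      stop("covariate matrix and cohort have different numbers of patients",
           call. = FALSE)
    }
    X <- cbind(X, mat[, hdps_names, drop = FALSE])
  }
  y <- cohort$exposure
  if (is.null(X) || ncol(X) == 0L) {
    fit <- stats::glm(y ~ 1, family = stats::binomial())
    used <- character()
    dropped <- character()
  } else {
    storage.mode(X) <- "double"
    fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                          family = stats::binomial())
    aliased <- is.na(fit$coefficients)
    dropped <- setdiff(names(fit$coefficients)[aliased], "(Intercept)")
    used <- setdiff(colnames(X), dropped)
    if (length(dropped) > 0L) {
      message("dropped ", length(dropped),
              " perfectly collinear covariate(s): ",
              paste(dropped, collapse = ", "))
    }
  }
  ps <- as.numeric(fit$fitted.values)
  if (!isTRUE(fit$converged)) {
    warning("propensity-score model did not converge", call. = FALSE)
  }
  eps <- 1e-10
  if (any(ps < eps | ps > 1 - eps)) {
    stop("separation detected: fitted propensity scores at machine 0/1; ",
         "consider trimming the sample or including fewer covariates",
         call. = FALSE)
  }
  structure(list(label = label,
                 covariates = used,
                 dropped = dropped,
                 ps = ps,
                 converged = isTRUE(fit$converged),
                 c_statistic = c_statistic(ps, y),
                 coefficients = fit$coefficients),
            class = "hdps_ps")
}

c_statistic <- function(ps, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(ps)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.hdps_ps <- function(x, ...) {
  cat(sprintf("Propensity score model '%s': %d covariates, c-statistic %.3f\n",
              x$label, length(x$covariates), x$c_statistic))
  if (length(x$dropped) > 0L) {
    cat("Aliased (dropped):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Inverse probability of treatment weights
#'
#' Unstabilized ATE weights: `1/ps` for the exposed, `1/(1-ps)` for the
#' unexposed. Stabilized weights multiply by the marginal exposure
#' probability of the patient's own group, shrinking the weight mean towards
#' 1 in each group without changing the weighted point estimate.
#'
#' @param ps An `hdps_ps` fit (or numeric vector of scores in (0,1)).
#' @param exposure Binary exposure vector.
#' @param stabilized Use stabilized weights? Default `FALSE`.
#' @return Numeric vector of positive weights.
#' @export
iptw_weights <- function(ps, exposure, stabilized = FALSE) {
  if (inherits(ps, "hdps_ps")) ps <- ps$ps
  stopifnot(all(ps > 0 & ps < 1), all(exposure %in% c(0L, 1L)),
            length(ps) == length(exposure))
  w <- ifelse(exposure == 1L, 1 / ps, 1 / (1 - ps))
  if (stabilized) {
    p_exp <- mean(exposure)
    w <- w * ifelse(exposure == 1L, p_exp, 1 - p_exp)
  }
  w
}

#' Construct / trim a weighted analysis set
#'
#' `weighted_analysis()` bundles a PS fit, its IPTW weights and the
#' patients analysed. `trim_ps()` removes patients whose propensity score
#' lies outside the given percentiles of the pooled PS distribution —
#' a common remedy when the tails show poor overlap (positivity concerns).
#' Percentiles are nearest-rank; the default `(0, 100)` performs no
#' trimming. Weights of the retained patients are left as fitted (the PS
#' model is not re-estimated on the trimmed sample).
#'
#' @param ps An `hdps_ps` fit.
#' @param cohort The cohort the PS was fitted on.
#' @param stabilized Passed to [iptw_weights()].
#' @return An object of class `hdps_weighted`: list with `ps`, `cohort`,
#'   `weights`, `keep` (logical vector), `n_trimmed`, `trim_rule`.
#' @export
weighted_analysis <- function(ps, cohort, stabilized = FALSE) {
  stopifnot(inherits(ps, "hdps_ps"), inherits(cohort, "hdps_cohort"),
            length(ps$ps) == nrow(cohort))
  structure(list(ps = ps, cohort = cohort,
                 weights = iptw_weights(ps, cohort$exposure, stabilized),
                 keep = rep(TRUE, nrow(cohort)),
                 n_trimmed = 0L,
                 trim_rule = "none",
                 stabilized = stabilized),
            class = "hdps_weighted")
}

#' @rdname weighted_analysis
#' @param analysis An `hdps_weighted` object.
#' @param lower_pct,upper_pct Percentile bounds in `[0, 100]`,
#'   `lower_pct < upper_pct`.
#' @export
trim_ps <- function(analysis, lower_pct = 0, upper_pct = 100) {
  stopifnot(inherits(analysis, "hdps_weighted"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("need 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  if (lower_pct == 0 && upper_pct == 100) return(analysis)
  ps <- analysis$ps$ps
  bounds <- stats::quantile(ps, c(lower_pct, upper_pct) / 100,
                            type = 1, names = FALSE)
  keep <- analysis$keep & ps >= bounds[1] & ps <= bounds[2]
  e <- analysis$cohort$exposure
  if (sum(keep & e == 1L) == 0L || sum(keep & e == 0L) == 0L) {
    stop("trimming would empty an exposure group", call. = FALSE)
  }
  analysis$keep <- keep
  analysis$n_trimmed <- sum(!keep)
  analysis$trim_rule <- sprintf("percentile [%g, %g]", lower_pct, upper_pct)
  message(sprintf("trimmed %d patient(s) (%d exposed, %d unexposed)",
                  sum(!keep), sum(!keep & e == 1L), sum(!keep & e == 0L)))
  analysis
}

#' IPTW-weighted Cox regression of the treatment effect
#'
#' Fits a Cox proportional-hazards model with exposure as the sole term,
#' weighted by the IPTW weights, with the Efron approximation for ties and
#' a robust (sandwich) variance treating the weights as fixed. Returns the
#' hazard ratio with its 95% confidence interval and confidence limit
#' ratio.
#'
#' @param cohort The cohort (`followup_time`, `event`, `exposure`).
#' @param weights Positive weights, one per patient; default all 1
#'   (unweighted/crude fit).
#' @param subset Logical vector of patients to analyse (e.g. after
#'   trimming); default all.
#' @param label Label carried into summaries.
#' @return An object of class `hdps_effect`: list with `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `clr`, `log_hr`, `se`, `n_events`, `n`,
#'   `label`.
#' @export
fit_weighted_cox <- function(cohort, weights = NULL, subset = NULL,
                             label = "effect") {
  stopifnot(inherits(cohort, "hdps_cohort"))
  n <- nrow(cohort)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(subset)) subset <- rep(TRUE, n)
  stopifnot(length(weights) == n, all(weights > 0), length(subset) == n)
  dat <- data.frame(time = cohort$followup_time,
                    event = cohort$event,
                    exposure = cohort$exposure,
                    w = weights)[subset, , drop = FALSE]
  if (sum(dat$event) == 0L) {
    stop("no outcome events in the analysed sample", call. = FALSE)
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ exposure,
                         data = dat, weights = w, robust = TRUE,
                         ties = "efron")
  b <- unname(stats::coef(fit)[1L])
  se <- sqrt(fit$var[1L, 1L])  # robust variance (coxph uses it when robust=TRUE)
  z <- stats::qnorm(0.975)
  lo <- exp(b - z * se)
  hi <- exp(b + z * se)
  structure(list(hazard_ratio = exp(b),
                 ci_lower = lo,
                 ci_upper = hi,
                 clr = compute_clr(lo, hi),
                 log_hr = b,
                 se = se,
                 n_events = sum(dat$event),
                 n = nrow(dat),
                 label = label),
            class = "hdps_effect")
}

#' @export
print.hdps_effect <- function(x, digits = 2, ...) {
  cat(sprintf("%s: HR %.*f (95%% CI %.*f-%.*f), CLR %.*f, %d events / %d patients\n",
              x$label, digits, x$hazard_ratio, digits, x$ci_lower,
              digits, x$ci_upper, digits, x$clr, x$n_events, x$n))
  invisible(x)
}

#' Confidence limit ratio
#'
#' The ratio of the upper to the lower bound of a confidence interval for a
#' ratio measure — a scale-invariant summary of the estimate's precision
#' (wider intervals give larger CLR; a degenerate interval gives 1).
#'
#' @param ci_lower,ci_upper Positive confidence bounds,
#'   `ci_lower <= ci_upper`.
#' @return `ci_upper / ci_lower`. Vectorised.
#' @examples
#' compute_clr(0.78, 1.28)
#' @export
compute_clr <- function(ci_lower, ci_upper) {
  if (any(ci_lower <= 0) || any(ci_upper <= 0)) {
    stop("confidence bounds must be positive", call. = FALSE)
  }
  if (any(ci_upper < ci_lower)) {
    stop("ci_upper must be >= ci_lower", call. = FALSE)
  }
  ci_upper / ci_lower
}
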