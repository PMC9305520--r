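#' Fit a high-dimensional propensity score analysis
#'
#' Runs the full HDPS procedure on a cohort and its declared data
#' dimensions:
#'
#' 1. restrict each dimension to the pre-exposure window;
#' 2. apply the per-dimension prevalence filter (top `n_top` codes);
#' 3. expand features into binary recurrence covariates
#'    (once / sporadic / frequent);
#' 4. prioritise covariates by the Bross bias multiplier (or by the
#'    exposure association only);
#' 5. select the top `k` covariates, fit the propensity score by logistic
#'    regression on the pre-defined plus selected HDPS covariates, derive
#'    inverse probability of treatment weights, and fit the IPTW-weighted
#'    Cox model with robust standard errors.
#'
#' Alongside the primary (pre-defined + HDPS weighted) analysis, the crude
#' and pre-defined-only analyses are always fitted for comparison.
#'
#' @param cohort An `hdps_cohort`.
#' @param dimensions List of `hdps_dimension` tables.
#' @param predefined Names of pre-defined covariates (columns of `cohort`);
#'   defaults to all extra cohort columns.
#' @param n_top Prevalence-filter size per dimension (default 200).
#' @param k Number of HDPS covariates to select (default 500).
#' @param ranking Prioritisation method: `"bross"` (default) or
#'   `"exposure_only"`.
#' @param lookback_days Pre-exposure window in days (default 365).
#' @param stabilized Use stabilized IPTW weights? Default `FALSE`.
#' @param trim Optional percentile trimming bounds `c(lower, upper)` on the
#'   PS distribution; default no trimming.
#' @param outcome Outcome association type for prioritisation: `"risk"`
#'   (default) or `"rate"`.
#' @param rank_by Prevalence-filter ranking, see [prevalence_filter()].
#' @param diagnostics Compute the balance table and overlap summary?
#'   Default `TRUE` (disable in tight simulation loops).
#' @return An object of class `hdps`: list with elements `cohort`,
#'   `covariates` (the full `hdps_covmatrix`), `prioritised` (ranked),
#'   `selected` (names), `ps` (list: `predefined`, `hdps`), `analysis`
#'   (`hdps_weighted` for the primary model), `effects` (list of
#'   `hdps_effect`: `crude`, `predefined`, `hdps`), `balance`, `overlap`,
#'   `params`.
#' @seealso [vary_k()], [remove_and_refit()], [build_report()],
#'   [generate_study()]
#' @examples
#' sim <- generate_study(sim_config(n_patients = 500, codes_per_dimension = 12,
#'                                  n_iv_codes = 2, n_noise_codes = 3,
#'                                  seed = 7))
#' fit <- hdps(sim$cohort, sim$dimensions, n_top = 50, k = 20,
#'             diagnostics = FALSE)
#' summary(fit)
#' @export
hdps <- function(cohort, dimensions,
                 predefined = attr(cohort, "predefined"),
                 n_top = 200, k = 500,
                 ranking = c("bross", "exposure_only"),
                 lookback_days = 365,
                 stabilized = FALSE,
                 trim = NULL,
                 outcome = c("risk", "rate"),
                 rank_by = "frequency",
                 diagnostics = TRUE) {
  stopifnot(inherits(cohort, "hdps_cohort"))
  ranking <- match.arg(ranking)
  outcome <- match.arg(outcome)
  if (is.null(predefined)) predefined <- character()

  covariates <- build_covariate_matrix(dimensions, cohort, n_top = n_top,
                                       lookback_days = lookback_days,
                                       rank_by = rank_by)
  prioritised <- rank_covariates(
    univariate_associations(covariates, cohort, outcome = outcome),
    method = ranking)
  selected <- select_top_k(prioritised, k)

  ps_pre <- fit_ps(cohort, predefined, label = "predefined")
  ps_hdps <- fit_ps(cohort, predefined, covariates, selected,
                    label = "predefined + HDPS")

  wa_pre <- weighted_analysis(ps_pre, cohort, stabilized)
  wa_hdps <- weighted_analysis(ps_hdps, cohort, stabilized)
  if (!is.null(trim)) {
    wa_hdps <- trim_ps(wa_hdps, trim[1], trim[2])
  }

  effects <- list(
    crude = fit_weighted_cox(cohort, label = "crude"),
    predefined = fit_weighted_cox(cohort, wa_pre$weights,
                                  label = "predefined only"),
    hdps = fit_weighted_cox(cohort, wa_hdps$weights, wa_hdps$keep,
                            label = "predefined + HDPS"))

  balance <- NULL
  overlap <- NULL
  if (diagnostics) {
    sel_mat <- covariates[, selected, drop = FALSE]
    sel_mat <- structure(sel_mat,
                         dictionary = attr(covariates, "dictionary"),
                         class = c("hdps_covmatrix", "matrix", "array"))
    balance <- balance_table(sel_mat, cohort,
                             weight_sets = list(predefined = wa_pre$weights,
                                                hdps = wa_hdps$weights),
                             predefined = predefined)
    overlap <- ps_overlap_summary(list(predefined = ps_pre,
                                       `predefined + HDPS` = ps_hdps),
                                  exposure = cohort$exposure)
  }

  structure(list(cohort = cohort,
                 covariates = covariates,
                 prioritised = prioritised,
                 selected = selected,
                 ps = list(predefined = ps_pre, hdps = ps_hdps),
                 analysis = wa_hdps,
                 effects = effects,
                 balance = balance,
                 overlap = overlap,
                 params = list(predefined = predefined, n_top = n_top,
                               k = k, ranking = ranking,
                               lookback_days = lookback_days,
                               stabilized = stabilized, trim = trim,
                               outcome = outcome, rank_by = rank_by,
                               dimensions = vapply(dimensions, attr,
                                                   character(1),
                                                   "dimension_name"))),
            class = "hdps")
}

# refit PS + weights + Cox for a different HDPS covariate set, reusing the
# stored prioritisation (never re-ranked)
refit_hdps <- function(fit, hdps_names, label) {
  ps <- fit_ps(fit$cohort, fit$params$predefined, fit$covariates,
               hdps_names, label = label)
  wa <- weighted_analysis(ps, fit$cohort, fit$params$stabilized)
  if (!is.null(fit$params$trim)) {
    wa <- trim_ps(wa, fit$params$trim[1], fit$params$trim[2])
  }
  fit_weighted_cox(fit$cohort, wa$weights, wa$keep, label = label)
}

#' @export
print.hdps <- function(x, ...) {
  cat("High-dimensional propensity score analysis\n")
  cat(sprintf("  Cohort: %d patients (%d exposed), %d events\n",
              nrow(x$cohort), sum(x$cohort$exposure), sum(x$cohort$event)))
  cat(sprintf("  Dimensions: %s\n",
              paste(x$params$dimensions, collapse = ", ")))
  cat(sprintf("  Covariates: %d generated, %d selected (top %d by %s)\n",
              nrow(x$prioritised), length(x$selected), x$params$k,
              x$params$ranking))
  print(x$effects$hdps)
  invisible(x)
}

#' @export
summary.hdps <- function(object, ...) {
  eff <- effect_table(object$effects)
  structure(list(effects = eff,
                 c_statistics = c(predefined = object$ps$predefined$c_statistic,
                                  hdps = object$ps$hdps$c_statistic),
                 overlap = if (!is.null(object$overlap))
                   object$overlap$overlap else NULL,
                 n_covariates = nrow(object$prioritised),
                 n_selected = length(object$selected),
                 params = object$params),
            class = "summary.hdps")
}

#' @export
print.summary.hdps <- function(x, ...) {
  cat("High-dimensional propensity score analysis\n\n")
  print(x$effects, row.names = FALSE, digits = 3)
  cat(sprintf("\nPS c-statistics: predefined %.3f, predefined + HDPS %.3f\n",
              x$c_statistics["predefined"], x$c_statistics["hdps"]))
  if (!is.null(x$overlap)) {
    cat(sprintf("PS overlap coefficients: predefined %.3f, predefined + HDPS %.3f\n",
                x$overlap[1], x$overlap[2]))
  }
  cat(sprintf("%d candidate covariates, %d selected\n",
              x$n_covariates, x$n_selected))
  invisible(x)
}

effect_table <- function(effects) {
  do.call(rbind, c(lapply(effects, function(e) {
    data.frame(analysis = e$label, hazard_ratio = e$hazard_ratio,
               ci_lower = e$ci_lower, ci_upper = e$ci_upper, clr = e$clr,
               n_events = e$n_events, stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
}

#' @export
coef.hdps <- function(object, ...) {
  c(log_hr = object$effects$hdps$log_hr)
}

#' @export
confint.hdps <- function(object, parm, level = 0.95, ...) {
  e <- object$effects$hdps
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(exp(e$log_hr + c(-1, 1) * z * e$se), nrow = 1,
              dimnames = list("hazard_ratio",
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}
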