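#' Sensitivity analysis over the number of selected covariates
#'
#' Re-fits the propensity score, weights and weighted Cox model for each
#' requested `k` on the *same* prioritised covariate list (prioritisation is
#' computed once by [hdps()] and never re-ranked). The crude and
#' pre-defined-only scenarios are always included for reference. A failure
#' in one scenario is recorded and the run continues.
#'
#' @param fit An [hdps()] fit.
#' @param k_values Vector of covariate counts to try (duplicates are
#'   dropped with a notice; the fit's own `k` is added automatically).
#' @return An object of class `hdps_sensitivity`: data frame with one row
#'   per scenario (`label`, `k`, `n_removed`, `n_hdps`, `hazard_ratio`,
#'   `ci_lower`, `ci_upper`, `clr`, `error`).
#' @export
vary_k <- function(fit, k_values = c(100, 250, 750)) {
  stopifnot(inherits(fit, "hdps"))
  if (length(k_values) == 0L || any(k_values < 0)) {
    stop("k_values must be non-empty and non-negative", call. = FALSE)
  }
  if (anyDuplicated(k_values)) {
    message("duplicate k values dropped")
    k_values <- unique(k_values)
  }
  k_values <- sort(unique(c(k_values, fit$params$k)))
  rows <- list(
    scenario_row("crude", NA_integer_, fit$effects$crude, n_total = 0L),
    scenario_row("predefined only", 0L, fit$effects$predefined,
                 n_total = 0L))
  for (k in k_values) {
    label <- sprintf("HDPS k = %d", k)
    eff <- try_scenario(fit, select_top_k(fit$prioritised, k), label)
    rows[[length(rows) + 1L]] <-
      scenario_row(label, k, eff, n_total = min(k, nrow(fit$prioritised)))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("hdps_sensitivity", "data.frame")
  out
}

try_scenario <- function(fit, hdps_names, label) {
  if (length(hdps_names) == 0L) return(fit$effects$predefined)
  tryCatch(refit_hdps(fit, hdps_names, label),
           error = function(e) structure(list(message = conditionMessage(e)),
                                         class = "hdps_scenario_error"))
}

scenario_row <- function(label, k, eff, n_total, n_removed = NA_integer_) {
  if (inherits(eff, "hdps_scenario_error")) {
    return(data.frame(label = label, k = k, n_removed = n_removed,
                      n_hdps = n_total, hazard_ratio = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      clr = NA_real_, log_hr = NA_real_,
                      error = eff$message, stringsAsFactors = FALSE))
  }
  data.frame(label = label, k = k, n_removed = n_removed, n_hdps = n_total,
             hazard_ratio = eff$hazard_ratio, ci_lower = eff$ci_lower,
             ci_upper = eff$ci_upper, clr = eff$clr, log_hr = eff$log_hr,
             error = NA_character_, stringsAsFactors = FALSE)
}

#' Incremental-adjustment curve over the prioritised covariates
#'
#' Estimates the treatment effect for `k = 0, stride, 2*stride, ..., N`
#' covariates (always including the endpoint `N`), tracing how the estimate
#' evolves as empirically selected covariates are added in rank order. A
#' numeric stabilisation summary — the maximum pairwise difference in log
#' hazard ratio over the upper half of the grid — operationalises the
#' visual judgement that the curve has settled.
#'
#' @param fit An [hdps()] fit.
#' @param stride Grid step (>= 1).
#' @return An object of class `hdps_incremental`: list with `estimates`
#'   (data frame indexed by `k`) and `stabilisation` (max `|delta log HR|`
#'   over the top half of the grid).
#' @export
incremental_curve <- function(fit, stride = 50) {
  stopifnot(inherits(fit, "hdps"))
  if (!is.numeric(stride) || stride < 1) {
    stop("stride must be >= 1", call. = FALSE)
  }
  N <- nrow(fit$prioritised)
  grid <- unique(c(seq(0L, N, by = stride), N))
  rows <- list()
  for (k in grid) {
    label <- sprintf("k = %d", k)
    eff <- if (k == 0L) fit$effects$predefined
           else try_scenario(fit, select_top_k(fit$prioritised, k), label)
    rows[[length(rows) + 1L]] <- scenario_row(label, k, eff, n_total = k)
  }
  est <- do.call(rbind, c(rows, make.row.names = FALSE))
  upper <- est[est$k >= stats::median(grid) & !is.na(est$log_hr), ]
  stab <- if (nrow(upper) >= 2L) {
    max(dist(upper$log_hr))
  } else NA_real_
  structure(list(estimates = est, stabilisation = stab, stride = stride),
            class = "hdps_incremental")
}

#' @export
print.hdps_incremental <- function(x, ...) {
  cat(sprintf("Incremental HDPS adjustment: %d grid points (stride %d)\n",
              nrow(x$estimates), x$stride))
  cat(sprintf("Stabilisation (max |delta log HR| over top half of grid): %.4f\n",
              x$stabilisation))
  invisible(x)
}

#' Remove covariates and re-fit the analysis
#'
#' Sensitivity analyses over potentially influential covariates. Exactly
#' one removal specification must be given:
#'
#' * `top_m_only`: keep only the `m` top-ranked HDPS covariates (plus
#'   pre-defined) — quantifies how much of the adjustment the most
#'   influential covariates carry;
#' * `rule`: an [near_iv_rule()]; covariates flagged as near-instruments
#'   are removed from the selected set;
#' * `remove_names`: explicit covariate names to remove from the selected
#'   set.
#'
#' Removal triggers full PS re-estimation and re-weighting (weights are
#' never reused across covariate sets).
#'
#' @param fit An [hdps()] fit.
#' @param top_m_only Integer `m`, or `NULL`.
#' @param rule An `hdps_neariv_rule`, or `NULL`.
#' @param remove_names Character vector, or `NULL`.
#' @param label Scenario label (defaults to a description of the removal).
#' @return An `hdps_sensitivity` data frame with one row.
#' @export
remove_and_refit <- function(fit, top_m_only = NULL, rule = NULL,
                             remove_names = NULL, label = NULL) {
  stopifnot(inherits(fit, "hdps"))
  spec <- c(!is.null(top_m_only), !is.null(rule), !is.null(remove_names))
  if (sum(spec) != 1L) {
    stop("give exactly one of top_m_only, rule, remove_names",
         call. = FALSE)
  }
  selected <- fit$selected
  if (!is.null(top_m_only)) {
    stopifnot(top_m_only >= 0)
    keep <- selected[seq_len(min(top_m_only, length(selected)))]
    if (is.null(label))
      label <- sprintf("top %d ranked only", top_m_only)
  } else if (!is.null(rule)) {
    flagged <- flag_near_ivs(fit$prioritised[fit$prioritised$name %in%
                                               selected, , drop = FALSE],
                             rule)
    keep <- setdiff(selected, flagged)
    if (is.null(label))
      label <- sprintf("near-IV removal (tau_e = %g, tau_o = %g)",
                       rule$tau_exposure, rule$tau_outcome)
  } else {
    keep <- setdiff(selected, remove_names)
    if (is.null(label)) label <- "explicit removal"
  }
  n_removed <- length(selected) - length(keep)
  eff <- if (length(keep) == 0L) fit$effects$predefined
         else if (identical(keep, selected)) fit$effects$hdps
         else try_scenario(fit, keep, label)
  out <- scenario_row(label, fit$params$k, eff, n_total = length(keep),
                      n_removed = n_removed)
  class(out) <- c("hdps_sensitivity", "data.frame")
  out
}

#' @export
print.hdps_sensitivity <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$hazard_ratio <- round(df$hazard_ratio, digits)
  df$ci_lower <- round(df$ci_lower, digits)
  df$ci_upper <- round(df$ci_upper, digits)
  df$clr <- round(df$clr, digits)
  df$log_hr <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity table as delimited text
#'
#' Columns mirror the standard reporting layout: scenario label, number of
#' covariates removed, total HDPS covariates, hazard ratio with CI, and
#' confidence limit ratio.
#'
#' @param x An `hdps_sensitivity` data frame (rows may be `rbind`-ed from
#'   several calls).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
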