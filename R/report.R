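#' Build the seven-item structured HDPS report
#'
#' Renders the key features and decisions of an HDPS analysis as a
#' seven-item structured document:
#'
#' 1. data dimensions declared;
#' 2. parameters for generating pre-exposure features (granularity,
#'    prevalence filter);
#' 3. feature recurrence assessment (cut-offs used);
#' 4. covariate prioritisation method;
#' 5. number of covariates selected, with justification;
#' 6. software used;
#' 7. diagnostics and sensitivity analyses conducted.
#'
#' Every item is always present; information not available from the run is
#' rendered as `"not reported"`, never silently omitted. The report is a
#' pure function of its inputs: regenerating it from the same fit gives an
#' identical document.
#'
#' @param fit An [hdps()] fit.
#' @param sensitivity Optional `hdps_sensitivity` table (e.g. rows from
#'   [vary_k()] and [remove_and_refit()]).
#' @param justification_k Optional free-text justification for the number
#'   of covariates selected.
#' @param granularity Optional description of the code granularity used
#'   when generating features (e.g. "3-digit ICD-10").
#' @return An object of class `hdps_report`: named list of seven character
#'   sections.
#' @export
build_report <- function(fit, sensitivity = NULL, justification_k = NULL,
                         granularity = NULL) {
  stopifnot(inherits(fit, "hdps"))
  p <- fit$params
  nr <- "not reported"

  dims <- p$dimensions
  dim_counts <- table(attr(fit$covariates, "dictionary")$dimension)
  item1 <- sprintf(
    "Data dimensions declared: %s. Covariates generated per dimension: %s.",
    paste(dims, collapse = ", "),
    paste(sprintf("%s (%d)", names(dim_counts), as.integer(dim_counts)),
          collapse = ", "))

  item2 <- sprintf(
    paste0("Features are codes recorded in the %d days before the index ",
           "date (index date excluded). Code granularity: %s. Prevalence ",
           "filter: top %d codes per dimension ranked by %s."),
    p$lookback_days, if (is.null(granularity)) nr else granularity,
    p$n_top,
    if (p$rank_by == "frequency") "number of patients with the code"
    else "closeness of prevalence to 50%")

  merges <- attr(fit$covariates, "merges")
  item3 <- sprintf(
    paste0("Recurrence assessed at three frequency cut-offs per code: ",
           ">= once, >= median count, >= 75th-percentile count (nearest-",
           "rank percentiles among patients with at least one occurrence); ",
           "%d identical column(s) collapsed."),
    if (is.null(merges)) 0L else nrow(merges))

  item4 <- sprintf(
    "Covariate prioritisation: %s.",
    if (p$ranking == "bross")
      "Bross bias multiplier (exposure-outcome prediction based)"
    else "exposure prediction only (|log covariate-exposure risk ratio|)")

  item5 <- sprintf(
    paste0("HDPS covariates selected: %d of %d candidates, augmenting %d ",
           "pre-defined covariate(s) (%s). Justification: %s."),
    length(fit$selected), nrow(fit$prioritised), length(p$predefined),
    if (length(p$predefined) > 0L) paste(p$predefined, collapse = ", ")
    else "none",
    if (is.null(justification_k)) nr else justification_k)

  item6 <- sprintf("Software: hdps R package version %s on R %s.",
                   as.character(utils::packageVersion("hdps")),
                   as.character(getRversion()))

  diag_bits <- character()
  if (!is.null(fit$overlap)) {
    diag_bits <- c(diag_bits, sprintf(
      "PS overlap coefficients: %s.",
      paste(sprintf("%s %.3f", names(fit$overlap$overlap),
                    fit$overlap$overlap), collapse = ", ")))
  }
  if (!is.null(fit$balance)) {
    wcol <- "asd_hdps"
    diag_bits <- c(diag_bits, sprintf(
      paste0("Covariate balance: %d/%d covariate(s) with unweighted ASD ",
             "> 10%%; max HDPS-weighted ASD %.2f%%."),
      sum(fit$balance$asd_unweighted > 10), nrow(fit$balance),
      max(fit$balance[[wcol]])))
  }
  if (is.null(fit$overlap) && is.null(fit$balance)) {
    diag_bits <- c(diag_bits, paste("Diagnostics:", nr))
  }
  sens_bit <- if (is.null(sensitivity)) {
    paste("Sensitivity analyses:", nr)
  } else {
    ok <- sensitivity[is.na(sensitivity$error), , drop = FALSE]
    sprintf(
      "Sensitivity analyses (%d scenario(s)): hazard ratios ranged %.2f-%.2f.",
      nrow(sensitivity), min(ok$hazard_ratio), max(ok$hazard_ratio))
  }
  item7 <- paste(c(diag_bits, sens_bit), collapse = " ")

  structure(list(
    `1. Data dimensions` = item1,
    `2. Pre-exposure feature generation` = item2,
    `3. Feature recurrence assessment` = item3,
    `4. Covariate prioritisation method` = item4,
    `5. Number of covariates selected` = item5,
    `6. Software` = item6,
    `7. Diagnostics and sensitivity analyses` = item7),
    class = "hdps_report")
}

#' @export
print.hdps_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.hdps_report <- function(x, ...) {
  out <- c("# HDPS analysis report", "")
  for (nm in names(x)) {
    out <- c(out, paste("##", nm), "", x[[nm]], "")
  }
  out
}

#' Write a report to disk
#'
#' Writes the rendered markdown document plus a machine-readable key-value
#' sidecar (`<path>.kv`, one `item<i>=<text>` line per item).
#'
#' @param report An `hdps_report`.
#' @param path Output path for the markdown document.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "hdps_report"))
  writeLines(format(report), path)
  kv <- sprintf("item%d=%s", seq_along(report),
                gsub("\n", " ", unlist(report)))
  writeLines(kv, paste0(path, ".kv"))
  invisible(path)
}
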