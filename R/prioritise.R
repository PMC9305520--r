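#' Bross bias multiplier for a binary confounder
#'
#' Upper-bound estimate of the multiplicative confounding bias that a binary
#' covariate could exert on the treatment--outcome association, given its
#' prevalence in the exposed (`pc1`) and unexposed (`pc0`) groups and its
#' risk ratio with the outcome (`rr_cd`):
#'
#' \deqn{B = \frac{p_{c1}(RR - 1) + 1}{p_{c0}(RR - 1) + 1}, \qquad
#'       RR = \max(RR_{CD},\ 1/RR_{CD})}
#'
#' The inversion of protective associations (`RR_CD < 1`) ensures that
#' protective confounders are scored by the magnitude of their outcome
#' association; without it they would rank spuriously low. Covariates are
#' prioritised by `|log B|`.
#'
#' @param pc1,pc0 Covariate prevalence in exposed / unexposed, in `[0, 1]`.
#' @param rr_cd Covariate--outcome risk ratio, `> 0`.
#' @return The bias multiplier, a positive number. Vectorised.
#' @examples
#' bross_bias(0.4, 0.2, 2)   # 1.4 / 1.2
#' bross_bias(0.3, 0.3, 5)   # equal prevalences: 1
#' @export
bross_bias <- function(pc1, pc0, rr_cd) {
  if (any(pc1 < 0 | pc1 > 1, na.rm = TRUE) ||
      any(pc0 < 0 | pc0 > 1, na.rm = TRUE)) {
    stop("pc1 and pc0 must be proportions in [0, 1]", call. = FALSE)
  }
  if (any(rr_cd <= 0, na.rm = TRUE)) {
    stop("rr_cd must be > 0", call. = FALSE)
  }
  rr <- pmax(rr_cd, 1 / rr_cd)
  (pc1 * (rr - 1) + 1) / (pc0 * (rr - 1) + 1)
}

risk_ratio_2x2 <- function(x11, x10, x01, x00) {
  # x11: group1 positive, x10: group1 negative; ratio of group1 vs group0 risk
  if (min(x11, x10, x01, x00) == 0) {
    x11 <- x11 + 0.1; x10 <- x10 + 0.1; x01 <- x01 + 0.1; x00 <- x00 + 0.1
  }
  r1 <- x11 / (x11 + x10)
  r0 <- x01 / (x01 + x00)
  list(p1 = r1, p0 = r0, rr = r1 / r0)
}

#' Univariate covariate-exposure and covariate-outcome associations
#'
#' For every binary covariate, tabulates its prevalence in the exposed and
#' unexposed groups (`pc1`, `pc0`), the covariate--exposure prevalence ratio
#' `rr_ce = pc1/pc0`, the covariate--outcome risk ratio `rr_cd` from the
#' binary event indicator, and the Bross bias multiplier. Whenever a 2x2
#' table contains a zero cell, 0.1 is added to each of its four cells before
#' the affected ratio is computed, so all ratios are finite and positive.
#'
#' Covariates constant across all patients carry no information and are
#' excluded (with a message). By default `rr_cd` is a cumulative-incidence
#' risk ratio ignoring follow-up time; `outcome = "rate"` uses person-time
#' incidence-rate ratios instead.
#'
#' @param covariates An `hdps_covmatrix` (or 0/1 matrix with column names).
#' @param cohort The cohort, aligned row-for-row with `covariates`.
#' @param outcome `"risk"` (default) or `"rate"`.
#' @return A data frame of class `hdps_prioritised` (unranked) with columns
#'   `name`, `dimension`, `code`, `cutoff`, `pc1`, `pc0`, `rr_ce`, `rr_cd`,
#'   `bias_m`, `abs_log_bias`.
#' @export
univariate_associations <- function(covariates, cohort,
                                    outcome = c("risk", "rate")) {
  stopifnot(inherits(cohort, "hdps_cohort"))
  outcome <- match.arg(outcome)
  mat <- unclass(covariates)
  if (is.null(colnames(mat))) stop("covariates must have column names",
                                   call. = FALSE)
  if (nrow(mat) != nrow(cohort)) {
    stop("covariate matrix and cohort have different numbers of patients",
         call. = FALSE)
  }
  e <- cohort$exposure
  d <- cohort$event
  t_fu <- cohort$followup_time
  dict <- attr(covariates, "dictionary")

  keep <- apply(mat, 2L, function(x) length(unique(x)) > 1L)
  if (any(!keep)) {
    message("excluded ", sum(!keep),
            " covariate(s) constant across all patients: ",
            paste(colnames(mat)[!keep], collapse = ", "))
  }
  mat <- mat[, keep, drop = FALSE]

  rows <- lapply(colnames(mat), function(nm) {
    x <- mat[, nm]
    ce <- risk_ratio_2x2(sum(x * e), sum((1 - x) * e),
                         sum(x * (1 - e)), sum((1 - x) * (1 - e)))
    if (outcome == "risk") {
      cd <- risk_ratio_2x2(sum(d * x), sum((1 - d) * x),
                           sum(d * (1 - x)), sum((1 - d) * (1 - x)))
      rr_cd <- cd$rr
    } else {
      ev1 <- sum(d * x); ev0 <- sum(d * (1 - x))
      pt1 <- sum(t_fu * x); pt0 <- sum(t_fu * (1 - x))
      if (min(ev1, ev0) == 0) { ev1 <- ev1 + 0.1; ev0 <- ev0 + 0.1 }
      rr_cd <- (ev1 / pt1) / (ev0 / pt0)
    }
    data.frame(name = nm, pc1 = ce$p1, pc0 = ce$p0, rr_ce = ce$rr,
               rr_cd = rr_cd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out)) {
    out <- data.frame(name = character(), pc1 = numeric(), pc0 = numeric(),
                      rr_ce = numeric(), rr_cd = numeric(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(dict)) {
    m <- match(out$name, dict$name)
    out$dimension <- dict$dimension[m]
    out$code <- dict$code[m]
    out$cutoff <- dict$cutoff[m]
  } else {
    out$dimension <- NA_character_
    out$code <- out$name
    out$cutoff <- NA_character_
  }
  out$bias_m <- bross_bias(out$pc1, out$pc0, out$rr_cd)
  out$abs_log_bias <- abs(log(out$bias_m))
  out <- out[c("name", "dimension", "code", "cutoff", "pc1", "pc0",
               "rr_ce", "rr_cd", "bias_m", "abs_log_bias")]
  class(out) <- c("hdps_prioritised", "data.frame")
  out
}

#' Rank covariates for selection
#'
#' `method = "bross"` ranks by descending `|log(bias multiplier)|`,
#' prioritising covariates with the highest potential to confound the
#' treatment--outcome association. `method = "exposure_only"` ranks by
#' descending `|log(rr_ce)|` — useful when outcome events are too few for
#' stable outcome associations. Ties are broken by covariate name; ranks are
#' a permutation of `1..N`.
#'
#' @param prioritised Output of [univariate_associations()].
#' @param method `"bross"` or `"exposure_only"`.
#' @return The same data frame with a `rank` column, sorted by rank.
#' @export
rank_covariates <- function(prioritised, method = c("bross", "exposure_only")) {
  stopifnot(inherits(prioritised, "hdps_prioritised"))
  method <- match.arg(method)
  if (nrow(prioritised) == 0L) stop("no covariates to rank", call. = FALSE)
  score <- switch(method,
                  bross = prioritised$abs_log_bias,
                  exposure_only = abs(log(prioritised$rr_ce)))
  ord <- order(-score, prioritised$name)
  out <- prioritised[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "ranking_method") <- method
  class(out) <- c("hdps_prioritised", "data.frame")
  out
}

#' Select the top-k ranked covariates
#'
#' @param ranked Ranked covariates from [rank_covariates()].
#' @param k Number of covariates to keep (`k = 0` gives a
#'   pre-defined-covariates-only analysis). If `k` exceeds the number
#'   available, all are returned with a notice.
#' @return Character vector of covariate names in rank order.
#' @export
select_top_k <- function(ranked, k) {
  stopifnot(inherits(ranked, "hdps_prioritised"))
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    stop("k must be a single count >= 0", call. = FALSE)
  }
  if (is.null(ranked$rank)) stop("covariates are not ranked yet", call. = FALSE)
  n <- nrow(ranked)
  if (k > n) {
    message("requested k = ", k, " but only ", n,
            " covariates available; returning all")
  }
  ranked$name[ranked$rank <= min(k, n)]
}

#' Write the prioritisation table
#'
#' All per-covariate association fields (the data behind the bias
#' distribution and association scatter diagnostics) as delimited text.
#'
#' @param prioritised An `hdps_prioritised` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prioritised <- function(prioritised, path) {
  utils::write.table(as.data.frame(prioritised), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
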