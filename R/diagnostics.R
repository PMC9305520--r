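#' Absolute standardised difference for a binary covariate
#'
#' Between-group imbalance on the percent scale:
#' `100 * |p1 - p0| / sqrt((p1(1-p1) + p0(1-p0)) / 2)`. When the pooled
#' variance is zero (both prevalences 0 or both 1) the difference is also
#' zero and the ASD is defined as 0. The conventional concern threshold is
#' 10%.
#'
#' @param p1,p0 Prevalences in the two groups, in `[0, 1]`. Vectorised.
#' @return Non-negative ASD in percent.
#' @export
asd_binary <- function(p1, p0) {
  if (any(p1 < 0 | p1 > 1) || any(p0 < 0 | p0 > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  v <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
  out <- ifelse(v == 0, 0, 100 * abs(p1 - p0) / sqrt(v))
  out
}

asd_continuous <- function(m1, m0, v1, v0) {
  v <- (v1 + v0) / 2
  ifelse(v == 0, 0, 100 * abs(m1 - m0) / sqrt(v))
}

weighted_mean_by <- function(x, w, g) {
  c(sum(w[g == 1L] * x[g == 1L]) / sum(w[g == 1L]),
    sum(w[g == 0L] * x[g == 0L]) / sum(w[g == 0L]))
}

#' Covariate balance table, unweighted and under IPTW weight sets
#'
#' One row per covariate with group prevalences (binary) or means
#' (continuous pre-defined covariates), the unweighted ASD, and one weighted
#' ASD column per supplied weight set. Weighted prevalences/means are
#' `sum(w*x)/sum(w)` within each exposure group. For comparability across
#' columns the ASD denominator always uses the *unweighted* pooled variance,
#' so weighting moves only the numerator (a `weighted_denominator = TRUE`
#' flag switches to fully weighted variances).
#'
#' @param covariates An `hdps_covmatrix` (binary columns), or `NULL`.
#' @param cohort The cohort; `predefined` columns may be binary or
#'   continuous.
#' @param weight_sets Named list of weight vectors (one per candidate
#'   model), each aligned to the cohort.
#' @param predefined Pre-defined covariate names to include.
#' @param weighted_denominator Use weighted group variances in the
#'   denominator of the weighted ASDs? Default `FALSE`.
#' @return A data frame of class `hdps_balance`: columns `name`, `type`,
#'   `p1`, `p0` (raw), `asd_unweighted`, then `asd_<set name>` per weight
#'   set, plus weighted prevalences `p1_<set>`, `p0_<set>`.
#' @export
balance_table <- function(covariates, cohort, weight_sets = list(),
                          predefined = character(),
                          weighted_denominator = FALSE) {
  stopifnot(inherits(cohort, "hdps_cohort"))
  e <- cohort$exposure
  for (nm in names(weight_sets)) {
    w <- weight_sets[[nm]]
    if (length(w) != nrow(cohort)) {
      stop("weight set '", nm, "' is not aligned to the cohort",
           call. = FALSE)
    }
    if (sum(w[e == 1L]) <= 0 || sum(w[e == 0L]) <= 0) {
      stop("weight set '", nm, "' has non-positive total in a group",
           call. = FALSE)
    }
  }
  cols <- list()
  types <- character()
  if (length(predefined) > 0L) {
    for (nm in predefined) {
      x <- as.numeric(cohort[[nm]])
      cols[[nm]] <- x
      types[nm] <- if (all(x %in% c(0, 1))) "binary" else "continuous"
    }
  }
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    mat <- unclass(covariates)
    for (nm in colnames(mat)) {
      cols[[nm]] <- as.numeric(mat[, nm])
      types[nm] <- "binary"
    }
  }
  if (length(cols) == 0L) stop("no covariates to balance", call. = FALSE)

  one <- rep(1, nrow(cohort))
  rows <- lapply(names(cols), function(nm) {
    x <- cols[[nm]]
    raw <- weighted_mean_by(x, one, e)
    v1_raw <- stats::var(x[e == 1L])
    v0_raw <- stats::var(x[e == 0L])
    if (types[nm] == "binary") {
      v1_raw <- raw[1] * (1 - raw[1]); v0_raw <- raw[2] * (1 - raw[2])
    }
    row <- data.frame(name = nm, type = types[nm],
                      p1 = raw[1], p0 = raw[2],
                      asd_unweighted =
                        asd_continuous(raw[1], raw[2], v1_raw, v0_raw),
                      stringsAsFactors = FALSE)
    for (ws in names(weight_sets)) {
      w <- weight_sets[[ws]]
      m <- weighted_mean_by(x, w, e)
      if (weighted_denominator) {
        if (types[nm] == "binary") {
          v1 <- m[1] * (1 - m[1]); v0 <- m[2] * (1 - m[2])
        } else {
          v1 <- weighted_mean_by((x - m[1])^2, w, e)[1]
          v0 <- weighted_mean_by((x - m[2])^2, w, e)[2]
        }
      } else {
        v1 <- v1_raw; v0 <- v0_raw
      }
      row[[paste0("asd_", ws)]] <- asd_continuous(m[1], m[2], v1, v0)
      row[[paste0("p1_", ws)]] <- m[1]
      row[[paste0("p0_", ws)]] <- m[2]
    }
    row
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("hdps_balance", "data.frame")
  out
}

#' Importance weight from a prioritisation rank
#'
#' For a ranked set of `N` HDPS covariates, the importance weight of the
#' covariate at `rank` is `((N + 1) - rank) / N`: 1 at rank 1, `1/N` at rank
#' `N`, strictly decreasing in rank. Pre-defined covariates are assigned
#' weight 1.
#'
#' @param rank Integer rank(s) in `1..N`.
#' @param N Size of the ranked set.
#' @return Importance weight(s) in `(0, 1]`.
#' @export
importance_weight <- function(rank, N) {
  stopifnot(is.numeric(rank), is.numeric(N), length(N) == 1L, N >= 1)
  if (any(rank < 1 | rank > N)) {
    stop("rank must lie in 1..N", call. = FALSE)
  }
  ((N + 1) - rank) / N
}

#' Mean absolute standardised difference
#'
#' Summarises a balance column as the plain mean of the ASDs, or the
#' importance-weighted mean `sum(w_r * ASD_r) / sum(w_r)` where `w_r` comes
#' from [importance_weight()] (pre-defined covariates contributing weight
#' 1). Putting more weight on highly ranked (stronger candidate) confounders
#' reflects that imbalance there is more likely to translate into bias.
#'
#' @param asd Numeric vector of ASDs.
#' @param weights Optional importance weights, same length; `NULL` (default)
#'   gives the unweighted mean.
#' @return A single number.
#' @export
mean_asd <- function(asd, weights = NULL) {
  if (length(asd) == 0L) stop("empty ASD set", call. = FALSE)
  if (is.null(weights)) return(mean(asd))
  stopifnot(length(weights) == length(asd), all(weights >= 0),
            sum(weights) > 0)
  sum(weights * asd) / sum(weights)
}

#' Propensity-score overlap summary
#'
#' Bins the fitted scores of each exposure group on a common grid over
#' `[0, 1]` and computes the overlap coefficient — the area under the
#' pointwise minimum of the two group densities (1 = identical
#' distributions, 0 = disjoint supports). Comparing the pre-defined-only
#' model with the pre-defined + HDPS model shows how much extra treatment
#' predictiveness the HDPS covariates contribute: a visible shift (lower
#' overlap) under the richer model means the HDPS captured between-patient
#' differences invisible to the investigator-specified covariates.
#'
#' @param ... One or more `hdps_ps` fits on the same cohort, ideally named.
#' @param exposure Binary exposure vector shared by the fits.
#' @param bins Number of equal-width bins over `[0, 1]` (default 100).
#' @return An object of class `hdps_overlap`: list with `densities` (long
#'   data frame: model, group, bin midpoint, density) and `overlap` (named
#'   numeric vector of overlap coefficients per model).
#' @export
ps_overlap_summary <- function(..., exposure, bins = 100) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "hdps_ps")) {
    fits <- fits[[1L]]
  }
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1),
                                           "hdps_ps")))
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, `[[`, character(1), "label")
  }
  breaks <- seq(0, 1, length.out = bins + 1L)
  width <- 1 / bins
  mids <- breaks[-1L] - width / 2
  dens_rows <- list()
  ov <- numeric(length(fits))
  names(ov) <- names(fits)
  for (nm in names(fits)) {
    ps <- fits[[nm]]$ps
    d1 <- graphics::hist(ps[exposure == 1L], breaks = breaks,
                         plot = FALSE)$density
    d0 <- graphics::hist(ps[exposure == 0L], breaks = breaks,
                         plot = FALSE)$density
    ov[nm] <- sum(pmin(d1, d0)) * width
    dens_rows[[nm]] <- data.frame(
      model = nm,
      group = rep(c("exposed", "unexposed"), each = bins),
      ps_mid = c(mids, mids),
      density = c(d1, d0),
      stringsAsFactors = FALSE)
  }
  structure(list(densities = do.call(rbind, c(dens_rows,
                                              make.row.names = FALSE)),
                 overlap = ov, bins = bins),
            class = "hdps_overlap")
}

#' @export
print.hdps_overlap <- function(x, ...) {
  cat("Propensity-score overlap coefficients:\n")
  for (nm in names(x$overlap)) {
    cat(sprintf("  %s: %.3f\n", nm, x$overlap[nm]))
  }
  invisible(x)
}

#' Prevalence-by-treatment-group scatter data
#'
#' Per covariate: prevalence among exposed vs unexposed, its prevalence
#' ratio, and a flag for covariates outside the reference band
#' `PR in [0.5, 2.0]`. An undefined PR (zero prevalence in a group) is
#' computed from continuity-corrected prevalences (0.1 added per cell of the
#' 2x2 table) and flagged.
#'
#' @param prioritised An `hdps_prioritised` table (its `pc1`/`pc0` are
#'   already continuity-corrected where needed).
#' @param pr_band Length-2 reference band on the prevalence ratio.
#' @return Data frame with `name`, `dimension`, `prev_exposed`,
#'   `prev_unexposed`, `pr`, `flagged`.
#' @export
prevalence_scatter <- function(prioritised, pr_band = c(0.5, 2.0)) {
  stopifnot(inherits(prioritised, "hdps_prioritised"))
  pr <- prioritised$pc1 / prioritised$pc0
  data.frame(name = prioritised$name,
             dimension = prioritised$dimension,
             prev_exposed = prioritised$pc1,
             prev_unexposed = prioritised$pc0,
             pr = pr,
             flagged = pr < pr_band[1] | pr > pr_band[2],
             stringsAsFactors = FALSE)
}

#' Distribution of absolute log Bross bias values by rank
#'
#' The rank-ordered `|log(bias multiplier)|` sequence for the selected
#' covariates, with dimension labels and per-dimension counts — the data
#' behind the prioritisation-distribution diagnostic. Inspecting the top of
#' this curve identifies covariates likely to dominate the PS model.
#'
#' @param ranked Ranked `hdps_prioritised` table.
#' @param top Restrict to the top `top` ranks (default all).
#' @return List of class `hdps_bias_distribution` with `values` (data frame
#'   rank, name, dimension, abs_log_bias, non-increasing in rank) and
#'   `dimension_counts`.
#' @export
bias_distribution <- function(ranked, top = Inf) {
  stopifnot(inherits(ranked, "hdps_prioritised"))
  if (is.null(ranked$rank)) stop("covariates are not ranked", call. = FALSE)
  df <- ranked[order(ranked$rank), c("rank", "name", "dimension",
                                     "abs_log_bias")]
  df <- df[df$rank <= top, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(values = df,
                 dimension_counts = table(df$dimension)),
            class = "hdps_bias_distribution")
}

#' Covariate-exposure vs covariate-outcome association strengths
#'
#' For each covariate, the strength of its exposure and outcome
#' associations, defined as the absolute value of the univariable risk ratio
#' minus 1 (`|rr - 1|`): 0 means no association, larger values a stronger
#' association in either direction. Covariates with a strong exposure but
#' weak outcome association (the top-left quadrant when strength of exposure
#' association is on the y-axis) behave empirically like instruments.
#'
#' @param prioritised An `hdps_prioritised` table.
#' @return Data frame with `name`, `dimension`, `strength_exposure`,
#'   `strength_outcome`, plus the log-scale analogues `abs_log_rr_ce`,
#'   `abs_log_rr_cd` used by the near-IV cut-offs.
#' @export
association_scatter <- function(prioritised) {
  stopifnot(inherits(prioritised, "hdps_prioritised"))
  data.frame(name = prioritised$name,
             dimension = prioritised$dimension,
             strength_exposure = abs(prioritised$rr_ce - 1),
             strength_outcome = abs(prioritised$rr_cd - 1),
             abs_log_rr_ce = abs(log(prioritised$rr_ce)),
             abs_log_rr_cd = abs(log(prioritised$rr_cd)),
             stringsAsFactors = FALSE)
}

#' Near-instrument detection rule
#'
#' A near-IV is a covariate strongly associated with exposure but weakly
#' with the outcome; adjusting for it cannot remove confounding and can
#' amplify bias and variance. The empirical rule flags a covariate iff
#' `|log(rr_ce)| > tau_exposure` and `|log(rr_cd)| < tau_outcome` (natural
#' logs). Proposed presets set `tau_exposure` to 1.5 or, more restrictively
#' (flagging more covariates), 1.1, both with `tau_outcome = 0.5`.
#'
#' @param tau_exposure Threshold on `|log rr_ce|` (default 1.1).
#' @param tau_outcome Threshold on `|log rr_cd|` (default 0.5).
#' @return An object of class `hdps_neariv_rule`.
#' @export
near_iv_rule <- function(tau_exposure = 1.1, tau_outcome = 0.5) {
  stopifnot(tau_exposure > 0, tau_outcome > 0)
  structure(list(tau_exposure = tau_exposure, tau_outcome = tau_outcome),
            class = "hdps_neariv_rule")
}

#' @rdname near_iv_rule
#' @param prioritised An `hdps_prioritised` table.
#' @param rule An `hdps_neariv_rule`.
#' @return `flag_near_ivs()`: character vector of flagged covariate names.
#' @export
flag_near_ivs <- function(prioritised, rule = near_iv_rule()) {
  stopifnot(inherits(prioritised, "hdps_prioritised"),
            inherits(rule, "hdps_neariv_rule"))
  hit <- abs(log(prioritised$rr_ce)) > rule$tau_exposure &
    abs(log(prioritised$rr_cd)) < rule$tau_outcome
  prioritised$name[hit]
}

#' Concept summary: selected covariates by dimension and code chapter
#'
#' Aggregates the selected covariates at the chapter level of the supplied
#' code hierarchy, counting each covariate once under its
#' (dimension, chapter) cell; codes absent from the hierarchy are counted
#' under `"unmapped"`. Communicates at a glance which clinical concepts the
#' empirically selected covariates capture.
#'
#' @param prioritised An `hdps_prioritised` table (typically restricted to
#'   the selected covariates).
#' @param hierarchy An `hdps_hierarchy` from [read_code_hierarchy()] /
#'   [as_code_hierarchy()].
#' @param names Optional subset of covariate names to summarise.
#' @return Data frame with `dimension`, `chapter`, `n`; `sum(n)` equals the
#'   number of summarised covariates.
#' @export
concept_summary <- function(prioritised, hierarchy, names = NULL) {
  stopifnot(inherits(prioritised, "hdps_prioritised"),
            inherits(hierarchy, "hdps_hierarchy"))
  df <- as.data.frame(prioritised)
  if (!is.null(names)) df <- df[df$name %in% names, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(dimension = character(), chapter = character(),
                      n = integer(), stringsAsFactors = FALSE))
  }
  df$chapter <- lookup_chapter(hierarchy, df$code)
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = list(dimension = df$dimension,
                                    chapter = df$chapter),
                          FUN = sum)
  agg[order(agg$dimension, -agg$n, agg$chapter), , drop = FALSE]
}
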