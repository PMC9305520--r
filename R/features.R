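#' Restrict a dimension to the pre-exposure window
#'
#' Keeps the records falling in the half-open window
#' `[index_date - lookback_days, index_date)` for each patient. Records on
#' the index date itself are excluded: same-day records are ambiguous with
#' respect to exposure start and must not leak post-exposure information
#' into the covariates.
#'
#' @param dimension An `hdps_dimension` table.
#' @param cohort The companion cohort (provides per-patient index dates).
#' @param lookback_days Length of the pre-exposure window in days
#'   (default 365, i.e. the year before cohort entry).
#' @return The restricted `hdps_dimension` (possibly empty).
#' @export
restrict_pre_exposure <- function(dimension, cohort, lookback_days = 365) {
  stopifnot(inherits(dimension, "hdps_dimension"),
            inherits(cohort, "hdps_cohort"))
  if (!is.numeric(lookback_days) || length(lookback_days) != 1L ||
      lookback_days < 1) {
    stop("lookback_days must be a single number >= 1", call. = FALSE)
  }
  idx <- cohort$index_date[match(dimension$patient_id, cohort$patient_id)]
  keep <- !is.na(idx) &
    dimension$date >= (idx - lookback_days) &
    dimension$date < idx
  out <- dimension[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dimension_name") <- attr(dimension, "dimension_name")
  class(out) <- class(dimension)
  out
}

#' Prevalence filter: retain the most common codes of a dimension
#'
#' Ranks codes by the number of distinct patients with at least one record
#' (multiple records of a code for one patient count once) and keeps the top
#' `n_top`. Ties are broken by lexicographic code order for determinism.
#'
#' A known variant ranks codes by closeness of prevalence to 50% instead of
#' raw frequency; `rank_by = "deviation"` selects it.
#'
#' @param dimension A (pre-exposure restricted) `hdps_dimension`.
#' @param cohort The companion cohort; supplies the denominator for
#'   prevalence.
#' @param n_top Maximum number of codes to keep (commonly 200 per
#'   dimension).
#' @param rank_by `"frequency"` (default; most common codes) or
#'   `"deviation"` (codes with prevalence closest to 0.5).
#' @return A data frame of class `hdps_features` with columns `dimension`,
#'   `code`, `n_patients`, `prevalence`, ordered by rank.
#' @export
prevalence_filter <- function(dimension, cohort, n_top = 200,
                              rank_by = c("frequency", "deviation")) {
  stopifnot(inherits(dimension, "hdps_dimension"),
            inherits(cohort, "hdps_cohort"))
  rank_by <- match.arg(rank_by)
  if (!is.numeric(n_top) || length(n_top) != 1L || n_top < 1) {
    stop("n_top must be a single count >= 1", call. = FALSE)
  }
  dim_name <- attr(dimension, "dimension_name")
  n <- nrow(cohort)
  if (nrow(dimension) == 0L) {
    out <- data.frame(dimension = character(), code = character(),
                      n_patients = integer(), prevalence = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("hdps_features", "data.frame")
    return(out)
  }
  pc <- unique(dimension[c("patient_id", "code")])
  counts <- table(pc$code)
  codes <- names(counts)
  n_pat <- as.integer(counts)
  prev <- n_pat / n
  score <- switch(rank_by,
                  frequency = n_pat,
                  deviation = -abs(prev - 0.5))
  ord <- order(-score, codes)
  take <- ord[seq_len(min(n_top, length(ord)))]
  out <- data.frame(dimension = dim_name, code = codes[take],
                    n_patients = n_pat[take], prevalence = prev[take],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hdps_features", "data.frame")
  out
}

#' Nearest-rank percentile of a count vector
#'
#' Percentile estimator used for the recurrence cut-offs: the smallest
#' element with rank at least `p/100 * n` (no interpolation), matching
#' integer count data.
#'
#' @param x Numeric vector (non-empty).
#' @param p Percentile in (0, 100].
#' @return A single value of `x`.
#' @keywords internal
nearest_rank <- function(x, p) {
  stopifnot(length(x) > 0L, p > 0, p <= 100)
  xs <- sort(x)
  unname(xs[ceiling(p / 100 * length(xs))])
}

#' Expand features into binary recurrence covariates
#'
#' For each filtered feature, per-patient occurrence counts in the
#' pre-exposure window are dichotomised at three frequency cut-offs,
#' giving up to three binary covariates per code:
#'
#' * `once`: count >= 1;
#' * `sporadic`: count >= median count among patients with >= 1 occurrence;
#' * `frequent`: count >= 75th percentile among patients with >= 1
#'   occurrence.
#'
#' Cut-offs use the nearest-rank percentile on patients with at least one
#' occurrence; computed over the whole cohort the median would be 0 for any
#' code with prevalence below 50% and every cut-off would collapse to
#' `once`. Columns that are exactly identical (e.g. when the median count is
#' 1) are collapsed, keeping the least stringent cut-off name; the merges
#' are recorded in `attr(x, "merges")`.
#'
#' @param dimension A pre-exposure restricted `hdps_dimension`.
#' @param features Features from [prevalence_filter()] on the same
#'   dimension.
#' @param cohort The companion cohort.
#' @return A binary matrix of class `hdps_covmatrix` (patients x
#'   covariates); rows follow cohort order and are named by `patient_id`.
#'   Column metadata (dimension, code, cut-off, threshold, prevalence) is in
#'   `attr(x, "dictionary")`; collapsed columns in `attr(x, "merges")`.
#' @export
assess_recurrence <- function(dimension, features, cohort) {
  stopifnot(inherits(dimension, "hdps_dimension"),
            inherits(features, "hdps_features"),
            inherits(cohort, "hdps_cohort"))
  dim_name <- attr(dimension, "dimension_name")
  n <- nrow(cohort)
  if (nrow(features) == 0L) {
    return(empty_covmatrix(cohort))
  }
  absent <- setdiff(features$code, dimension$code)
  if (length(absent) > 0L) {
    stop("feature code(s) absent from dimension '", dim_name, "': ",
         paste(absent, collapse = ", "),
         " (features must come from prevalence_filter on the same dimension)",
         call. = FALSE)
  }
  events <- dimension[dimension$code %in% features$code, , drop = FALSE]
  counts <- table(factor(events$patient_id, levels = cohort$patient_id),
                  factor(events$code, levels = features$code))
  counts <- matrix(as.integer(counts), nrow = n,
                   dimnames = list(cohort$patient_id, features$code))

  cutoffs <- c("once", "sporadic", "frequent")
  cols <- list()
  dict <- list()
  merges <- list()
  for (j in seq_len(nrow(features))) {
    code <- features$code[j]
    cnt <- counts[, code]
    pos <- cnt[cnt >= 1L]
    thr <- c(once = 1,
             sporadic = nearest_rank(pos, 50),
             frequent = nearest_rank(pos, 75))
    ind <- lapply(cutoffs, function(k) as.integer(cnt >= thr[[k]]))
    names(ind) <- cutoffs
    kept <- "once"
    for (k in cutoffs[-1L]) {
      dup_of <- NULL
      for (kk in kept) {
        if (identical(ind[[kk]], ind[[k]])) { dup_of <- kk; break }
      }
      if (is.null(dup_of)) {
        kept <- c(kept, k)
      } else {
        merges[[length(merges) + 1L]] <- data.frame(
          dimension = dim_name, code = code, dropped = k, kept_as = dup_of,
          stringsAsFactors = FALSE)
      }
    }
    for (k in kept) {
      nm <- covariate_name(dim_name, code, k)
      cols[[nm]] <- ind[[k]]
      dict[[nm]] <- data.frame(
        name = nm, dimension = dim_name, code = code, cutoff = k,
        threshold = unname(thr[[k]]), prevalence = mean(ind[[k]]),
        stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- cohort$patient_id
  structure(mat,
            dictionary = do.call(rbind, c(dict, make.row.names = FALSE)),
            merges = if (length(merges) > 0L)
              do.call(rbind, c(merges, make.row.names = FALSE))
            else NULL,
            class = c("hdps_covmatrix", class(mat)))
}

covariate_name <- function(dimension, code, cutoff) {
  paste(dimension, code, cutoff, sep = "__")
}

empty_covmatrix <- function(cohort) {
  mat <- matrix(integer(0), nrow = nrow(cohort), ncol = 0L,
                dimnames = list(cohort$patient_id, NULL))
  structure(mat,
            dictionary = data.frame(name = character(),
                                    dimension = character(),
                                    code = character(), cutoff = character(),
                                    threshold = numeric(),
                                    prevalence = numeric(),
                                    stringsAsFactors = FALSE),
            merges = NULL,
            class = c("hdps_covmatrix", "matrix", "array"))
}

#' Build the full covariate matrix across data dimensions
#'
#' Convenience wrapper running [restrict_pre_exposure()],
#' [prevalence_filter()] and [assess_recurrence()] for each declared
#' dimension and binding the per-dimension covariate matrices together.
#'
#' @param dimensions A list of `hdps_dimension` tables.
#' @param cohort The cohort.
#' @param n_top Prevalence-filter size per dimension.
#' @param lookback_days Pre-exposure window length in days.
#' @param rank_by Passed to [prevalence_filter()].
#' @return An `hdps_covmatrix` spanning all dimensions.
#' @export
build_covariate_matrix <- function(dimensions, cohort, n_top = 200,
                                   lookback_days = 365,
                                   rank_by = "frequency") {
  stopifnot(is.list(dimensions), length(dimensions) >= 1L)
  parts <- lapply(dimensions, function(d) {
    dr <- restrict_pre_exposure(d, cohort, lookback_days)
    feats <- prevalence_filter(dr, cohort, n_top, rank_by = rank_by)
    assess_recurrence(dr, feats, cohort)
  })
  mat <- do.call(cbind, lapply(parts, unclass))
  rownames(mat) <- cohort$patient_id
  dict <- do.call(rbind, c(lapply(parts, attr, "dictionary"),
                           make.row.names = FALSE))
  merges <- do.call(rbind, c(Filter(Negate(is.null),
                                    lapply(parts, attr, "merges")),
                             make.row.names = FALSE))
  structure(mat, dictionary = dict,
            merges = if (!is.null(merges) && nrow(merges) > 0L) merges else NULL,
            class = c("hdps_covmatrix", "matrix", "array"))
}

#' Write a covariate matrix and its dictionary
#'
#' @param x An `hdps_covmatrix`.
#' @param path Output path for the patients x covariates table.
#' @param dictionary_path Optional output path for the covariate dictionary
#'   (name, dimension, code, cutoff, threshold, prevalence).
#' @return `path`, invisibly.
#' @export
write_covariate_matrix <- function(x, path, dictionary_path = NULL) {
  stopifnot(inherits(x, "hdps_covmatrix"))
  df <- data.frame(patient_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  if (!is.null(dictionary_path)) {
    utils::write.table(attr(x, "dictionary"), dictionary_path, sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
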