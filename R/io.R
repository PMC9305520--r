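#' Read a cohort table
#'
#' Reads a delimited file describing the study cohort: one row per patient
#' with the columns `patient_id`, `index_date`, `exposure`, `event`,
#' `followup_time`, plus any number of additional columns treated as
#' pre-defined covariates (binary or continuous). Validation enforces the
#' data model every downstream stage relies on: unique patient identifiers,
#' strictly binary exposure and event indicators, strictly positive
#' follow-up times, and at least one patient in each exposure group.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A `data.frame` of class `hdps_cohort`. `index_date` is a `Date`;
#'   `exposure` and `event` are integer 0/1. The names of the extra columns
#'   are available via `attr(x, "predefined")`.
#' @seealso [read_dimension()], [write_cohort()]
#' @export
read_cohort <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_cohort(df)
}

#' Coerce a data frame to a validated cohort table
#'
#' @param df A data frame with the columns described in [read_cohort()].
#' @return A validated `hdps_cohort` data frame.
#' @export
as_cohort <- function(df) {
  required <- c("patient_id", "index_date", "exposure", "event",
                "followup_time")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  dup <- df$patient_id[duplicated(df$patient_id)]
  if (length(dup) > 0L) {
    stop("duplicated patient_id in cohort: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  df$index_date <- parse_dates(df$index_date, "index_date")
  for (col in c("exposure", "event")) {
    v <- df[[col]]
    if (!all(v %in% c(0L, 1L))) {
      bad <- which(!(v %in% c(0L, 1L)))[1L]
      stop(sprintf("column '%s' must be binary 0/1; row %d has value '%s'",
                   col, bad, v[bad]), call. = FALSE)
    }
    df[[col]] <- as.integer(v)
  }
  if (!is.numeric(df$followup_time) || any(df$followup_time <= 0)) {
    stop("column 'followup_time' must be numeric and > 0", call. = FALSE)
  }
  if (length(unique(df$exposure)) < 2L) {
    stop("both exposure groups must be non-empty", call. = FALSE)
  }
  attr(df, "predefined") <- setdiff(names(df), required)
  class(df) <- c("hdps_cohort", "data.frame")
  df
}

parse_dates <- function(x, what) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d)) {
    bad <- which(is.na(d))[1L]
    stop(sprintf("unparseable %s '%s' at line %d (expected ISO-8601 YYYY-MM-DD)",
                 what, as.character(x)[bad], bad), call. = FALSE)
  }
  d
}

#' Read a data-dimension event table
#'
#' A data dimension is a named stream of coded events capturing one aspect of
#' care (e.g. clinical diagnoses, referrals, prescriptions). The file holds
#' one row per event with columns `patient_id`, `code`, `date`. Records for
#' patients absent from the companion cohort are dropped (orphans), with the
#' count reported via a message.
#'
#' @param path Path to a delimited text file with a header row.
#' @param name Label for the dimension (e.g. `"clinical"`).
#' @param cohort A cohort from [read_cohort()] / [as_cohort()].
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A `data.frame` of class `hdps_dimension` with columns
#'   `patient_id`, `code`, `date` and attribute `dimension_name`.
#' @export
read_dimension <- function(path, name, cohort, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  as_dimension(df, name, cohort)
}

#' Coerce a data frame of coded events to a validated dimension table
#'
#' @param df Data frame with columns `patient_id`, `code`, `date`.
#' @inheritParams read_dimension
#' @return A validated `hdps_dimension` data frame.
#' @export
as_dimension <- function(df, name, cohort) {
  stopifnot(is.character(name), length(name) == 1L)
  required <- c("patient_id", "code", "date")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("dimension file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  df$patient_id <- as.character(df$patient_id)
  df$code <- as.character(df$code)
  if (nrow(df) > 0L && any(!nzchar(df$code))) {
    stop("dimension '", name, "' contains empty code strings", call. = FALSE)
  }
  df$date <- parse_dates(df$date, "event date")
  keep <- df$patient_id %in% cohort$patient_id
  n_orphan <- sum(!keep)
  if (n_orphan > 0L) {
    message(sprintf("dimension '%s': dropped %d orphan record(s) for patients not in cohort",
                    name, n_orphan))
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dimension_name") <- name
  attr(df, "n_orphans") <- n_orphan
  class(df) <- c("hdps_dimension", "data.frame")
  df
}

#' Read a code hierarchy (code to chapter mapping)
#'
#' Maps codes to high-level chapter labels (e.g. ICD-10 chapters, BNF
#' chapters) for concept summaries. The map is total: looking up an unmapped
#' code returns `"unmapped"` rather than failing.
#'
#' @param path Two-column delimited file with header, columns `code` and
#'   `chapter`.
#' @param sep Field delimiter.
#' @return An object of class `hdps_hierarchy`; use [lookup_chapter()].
#' @export
read_code_hierarchy <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) {
    stop("code hierarchy file must have two columns (code, chapter)",
         call. = FALSE)
  }
  names(df)[1:2] <- c("code", "chapter")
  as_code_hierarchy(df$code, df$chapter)
}

#' Build a code hierarchy from vectors
#'
#' @param codes Character vector of codes.
#' @param chapters Character vector of chapter labels, same length.
#' @return An object of class `hdps_hierarchy`.
#' @export
as_code_hierarchy <- function(codes, chapters) {
  stopifnot(length(codes) == length(chapters))
  codes <- as.character(codes)
  chapters <- as.character(chapters)
  dup <- duplicated(codes)
  if (any(dup)) {
    conflict <- vapply(unique(codes[dup]), function(cd) {
      length(unique(chapters[codes == cd])) > 1L
    }, logical(1))
    if (any(conflict)) {
      stop("conflicting chapter assignments for code(s): ",
           paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)
    }
    keep <- !dup
    codes <- codes[keep]
    chapters <- chapters[keep]
  }
  map <- stats::setNames(chapters, codes)
  structure(list(map = map), class = "hdps_hierarchy")
}

#' Look up chapter labels for codes
#'
#' @param hierarchy An `hdps_hierarchy`.
#' @param codes Character vector of codes.
#' @return Character vector of chapter labels; `"unmapped"` for codes absent
#'   from the map.
#' @export
lookup_chapter <- function(hierarchy, codes) {
  stopifnot(inherits(hierarchy, "hdps_hierarchy"))
  out <- unname(hierarchy$map[as.character(codes)])
  out[is.na(out)] <- "unmapped"
  out
}

#' Write cohort / dimension tables as delimited text
#'
#' Writers emit a header row and ISO-8601 dates, so that a write/read
#' round-trip reproduces the table exactly.
#'
#' @param cohort A cohort table.
#' @param dimension A dimension table.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  df <- as.data.frame(cohort)
  df$index_date <- format(df$index_date, "%Y-%m-%d")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
write_dimension <- function(dimension, path, sep = ",") {
  df <- as.data.frame(dimension)
  df$date <- format(df$date, "%Y-%m-%d")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.hdps_cohort <- function(x, ...) {
  cat(sprintf("HDPS cohort: %d patients (%d exposed, %d unexposed), %d events\n",
              nrow(x), sum(x$exposure), sum(1 - x$exposure), sum(x$event)))
  pd <- attr(x, "predefined")
  if (length(pd) > 0L) {
    cat("Pre-defined covariates:", paste(pd, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.hdps_dimension <- function(x, ...) {
  cat(sprintf("HDPS data dimension '%s': %d records, %d distinct codes, %d patients\n",
              attr(x, "dimension_name"), nrow(x),
              length(unique(x$code)), length(unique(x$patient_id))))
  invisible(x)
}
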