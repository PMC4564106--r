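#' Construct a survival dataset
#'
#' Bundles follow-up times, event indicators and an optional covariate matrix
#' into the container consumed by every other function in the package.
#'
#' @param times Numeric vector of non-negative follow-up durations, one per
#'   subject, all in the same unit (e.g. days).
#' @param events Integer/numeric vector of the same length; 1 means the event
#'   was observed, 0 means the subject was right-censored at `times`.
#' @param covariates Optional numeric matrix (or data frame coercible to one)
#'   with one row per subject. May be `NULL` for curve-only computations.
#'
#' @return An object of class `survival_dataset`: a list with elements
#'   `times`, `events` and `covariates`.
#' @export
#' @examples
#' d <- survival_dataset(c(5, 10, 12), c(1, 0, 1))
#' n_subjects(d)
survival_dataset <- function(times, events, covariates = NULL) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  if (length(times) < 1L) {
    stop("survival_dataset: need at least one subject", call. = FALSE)
  }
  if (length(times) != length(events)) {
    stop("survival_dataset: times and events must have equal length", call. = FALSE)
  }
  if (anyNA(times) || any(times < 0)) {
    stop("survival_dataset: times must be non-negative and non-missing", call. = FALSE)
  }
  if (anyNA(events) || !all(events %in% c(0, 1))) {
    stop("survival_dataset: events must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.numeric(covariates)) {
      stop("survival_dataset: covariates must be numeric", call. = FALSE)
    }
    if (nrow(covariates) != length(times)) {
      stop("survival_dataset: covariates must have one row per subject", call. = FALSE)
    }
  }
  structure(
    list(times = times, events = events, covariates = covariates),
    class = "survival_dataset"
  )
}

#' Number of subjects in a survival dataset
#' @param data A `survival_dataset`.
#' @return Integer subject count.
#' @export
n_subjects <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  length(data$times)
}

#' Subset a survival dataset by row
#'
#' @param data A `survival_dataset`.
#' @param idx Integer or logical index over subjects.
#' @return A `survival_dataset` restricted to the selected subjects.
#' @export
subset_dataset <- function(data, idx) {
  stopifnot(inherits(data, "survival_dataset"))
  survival_dataset(
    data$times[idx],
    data$events[idx],
    if (is.null(data$covariates)) NULL else data$covariates[idx, , drop = FALSE]
  )
}

#' @export
print.survival_dataset <- function(x, ...) {
  n <- length(x$times)
  cens <- sum(x$events == 0)
  cat(sprintf(
    "<survival_dataset> %d subjects, %d censored (%.0f%%), %s covariates\n",
    n, cens, 100 * cens / n,
    if (is.null(x$covariates)) "no" else ncol(x$covariates)
  ))
  invisible(x)
}

#' Read a survival table from CSV
#'
#' The CSV dialect used throughout the package: comma-separated with a header
#' row, required columns `time` and `event` (0/1), and any further columns
#' treated as covariates. Empty cells or `NA` denote missing values.
#'
#' @param path Path to the CSV file.
#' @return A list with `data` (a `survival_dataset` without covariates),
#'   `covariates` (a data frame of the remaining columns, possibly with
#'   missing values and factors — run it through the preprocessing pipeline
#'   before modelling) and `ids` (row identifiers: an `id` column if present,
#'   else row numbers).
#' @export
read_survival_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!all(c("time", "event") %in% names(df))) {
    missing <- setdiff(c("time", "event"), names(df))
    stop(sprintf(
      "read_survival_csv: required column(s) missing: %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  ids <- if ("id" %in% names(df)) df$id else seq_len(nrow(df))
  cov_cols <- setdiff(names(df), c("time", "event", "id"))
  list(
    data = survival_dataset(df$time, df$event),
    covariates = df[, cov_cols, drop = FALSE],
    ids = ids
  )
}

#' Write a survival table to CSV
#'
#' @param data A `survival_dataset`.
#' @param path Output path.
#' @param covariates Optional data frame of covariate columns to include
#'   (defaults to the dataset's own covariate matrix, if any).
#' @param extra Optional data frame of additional columns (e.g. latent labels).
#' @return The path, invisibly.
#' @export
write_survival_csv <- function(data, path, covariates = NULL, extra = NULL) {
  stopifnot(inherits(data, "survival_dataset"))
  if (is.null(covariates) && !is.null(data$covariates)) {
    covariates <- as.data.frame(data$covariates)
  }
  df <- data.frame(time = data$times, event = data$events)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
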