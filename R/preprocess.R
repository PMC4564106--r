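#' Preprocessing pipeline
#'
#' The covariate pipeline applied to every dataset before training: categorical
#' columns are expanded into one indicator per level, missing values are
#' replaced by the column mean, and every column is z-normalized. All
#' statistics are fitted on training data only and re-applied verbatim to new
#' data, so no information leaks from validation or test sets.
#'
#' @name preprocess
NULL

#' Expand categorical columns into per-level indicators
#'
#' Each declared categorical column with `c` observed levels is replaced by
#' `c` binary columns named `column.level`, one per level; rows sum to 1 where
#' the original value is non-missing. A missing categorical value yields
#' missing indicators (imputed downstream). When `levels_map` is supplied
#' (apply mode) the stored level sets are used; values outside them map to
#' all-zero indicators.
#'
#' @param table A data frame.
#' @param categorical_columns Character vector of column names to expand.
#' @param levels_map Optional named list of level vectors fitted previously.
#' @return A list with `table` (the expanded data frame) and `levels_map`.
#' @export
binarize_categoricals <- function(table, categorical_columns,
                                  levels_map = NULL) {
  unknown <- setdiff(categorical_columns, names(table))
  if (length(unknown)) {
    stop(sprintf("binarize_categoricals: unknown column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fitted <- list()
  out <- table
  for (col in categorical_columns) {
    vals <- as.character(table[[col]])
    levs <- if (!is.null(levels_map)) levels_map[[col]] else
      sort(unique(vals[!is.na(vals)]))
    ind <- matrix(0, nrow = nrow(table), ncol = length(levs),
                  dimnames = list(NULL, paste(col, levs, sep = ".")))
    for (j in seq_along(levs)) ind[, j] <- as.numeric(vals == levs[j])
    ind[is.na(vals), ] <- NA_real_
    pos <- match(col, names(out))
    out <- cbind(out[, seq_len(pos - 1L), drop = FALSE],
                 as.data.frame(ind),
                 out[, -seq_len(pos), drop = FALSE])
    fitted[[col]] <- levs
  }
  list(table = out, levels_map = if (is.null(levels_map)) fitted else levels_map)
}

#' Mean imputation
#'
#' Replaces missing entries with the column mean. In fit mode (no `means`)
#' the means are computed from the observed values of each column; in apply
#' mode the stored training means are used unchanged.
#'
#' @param table A numeric data frame.
#' @param means Optional named numeric vector of stored imputation values.
#' @return A list with `table` (no missing values) and `means`.
#' @export
impute_mean <- function(table, means = NULL) {
  if (is.null(means)) {
    means <- vapply(table, function(x) mean(x, na.rm = TRUE), numeric(1))
    if (any(is.nan(means))) {
      bad <- names(means)[is.nan(means)]
      stop(sprintf("impute_mean: column(s) entirely missing at fit time: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  for (col in names(table)) {
    miss <- is.na(table[[col]])
    if (any(miss)) table[[col]][miss] <- means[[col]]
  }
  list(table = table, means = means)
}

#' Z-normalization
#'
#' Transforms each column to `(x - mean) / sd` using the sample (n - 1)
#' standard deviation. In fit mode columns with zero variance are dropped
#' with a warning and recorded; in apply mode the stored statistics and drop
#' list are reused so train and test land on the same scale.
#'
#' @param table A numeric, missing-free data frame.
#' @param params Optional list with `center`, `scale`, `dropped` from a
#'   previous fit.
#' @return A list with `table` and `params` (`center`, `scale`, `dropped`).
#' @export
normalize_columns <- function(table, params = NULL) {
  if (is.null(params)) {
    center <- vapply(table, mean, numeric(1))
    scale <- vapply(table, stats::sd, numeric(1))
    dropped <- names(table)[is.na(scale) | scale == 0]
    if (length(dropped)) {
      warning(sprintf("normalize_columns: dropping constant column(s): %s",
                      paste(dropped, collapse = ", ")), call. = FALSE)
    }
    keep <- setdiff(names(table), dropped)
    params <- list(center = center[keep], scale = scale[keep], dropped = dropped)
  }
  table <- table[, setdiff(names(table), params$dropped), drop = FALSE]
  missing_cols <- setdiff(names(params$center), names(table))
  if (length(missing_cols)) {
    stop(sprintf("normalize_columns: column(s) missing from table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  table <- table[, names(params$center), drop = FALSE]
  for (col in names(params$center)) {
    table[[col]] <- (table[[col]] - params$center[[col]]) / params$scale[[col]]
  }
  list(table = table, params = params)
}

#' Fit the full preprocessing pipeline
#'
#' Composes binarization, mean imputation and z-normalization on a raw
#' covariate table and captures every fitted statistic for later reuse.
#'
#' @param table Raw covariate data frame (numeric and categorical columns,
#'   `NA` for missing).
#' @param categorical_columns Character vector of columns to binarize.
#' @return A list with `x` (fully numeric, missing-free matrix) and `params`
#'   (a `preprocess_params` object).
#' @export
preprocess_fit <- function(table, categorical_columns = character(0)) {
  b <- binarize_categoricals(table, categorical_columns)
  i <- impute_mean(b$table)
  n <- normalize_columns(i$table)
  params <- structure(
    list(categorical_columns = categorical_columns, levels_map = b$levels_map,
         means = i$means, center = n$params$center, scale = n$params$scale,
         dropped = n$params$dropped),
    class = "preprocess_params"
  )
  list(x = as.matrix(n$table), params = params)
}

#' Apply fitted preprocessing parameters to new data
#'
#' @param table Raw covariate data frame with the same columns as at fit time.
#' @param params A `preprocess_params` from [preprocess_fit()].
#' @return A numeric matrix on the training scale.
#' @export
preprocess_apply <- function(table, params) {
  stopifnot(inherits(params, "preprocess_params"))
  b <- binarize_categoricals(table, params$categorical_columns,
                             levels_map = params$levels_map)
  i <- impute_mean(b$table, means = params$means)
  n <- normalize_columns(i$table,
                         params = params[c("center", "scale", "dropped")])
  as.matrix(n$table)
}

serialize_preprocess <- function(params) {
  stopifnot(inherits(params, "preprocess_params"))
  list(
    categorical_columns = params$categorical_columns,
    levels_map = params$levels_map,
    means = as.list(params$means),
    center = as.list(params$center),
    scale = as.list(params$scale),
    dropped = params$dropped
  )
}

deserialize_preprocess <- function(obj) {
  structure(
    list(
      categorical_columns = as.character(unlist(obj$categorical_columns)),
      levels_map = lapply(obj$levels_map, as.character),
      means = unlist(obj$means),
      center = unlist(obj$center),
      scale = unlist(obj$scale),
      dropped = as.character(unlist(obj$dropped))
    ),
    class = "preprocess_params"
  )
}

#' Censoring-stratified train/test split
#'
#' Randomly assigns a fraction of subjects to the test set, stratified on the
#' event indicator so the censored fraction of the test set stays within one
#' subject of the overall censored fraction. Allocation rounds to the nearest
#' integer per stratum, with any residual against the overall target assigned
#' to the larger stratum.
#'
#' @param data A `survival_dataset`.
#' @param test_fraction Fraction held out (default 1/4).
#' @return A list with `train`, `test` (both `survival_dataset`s) and the
#'   index vectors `train_idx`, `test_idx` into the original subjects.
#' @export
split_stratified <- function(data, test_fraction = 0.25) {
  stopifnot(inherits(data, "survival_dataset"))
  if (test_fraction < 0 || test_fraction >= 1) {
    stop("split_stratified: test_fraction must lie in [0, 1)", call. = FALSE)
  }
  n <- length(data$times)
  strata <- split(seq_len(n), data$events)
  sizes <- lengths(strata)
  if (any(sizes < 2L)) {
    warning("split_stratified: a censoring stratum has fewer than 2 subjects; ",
            "best-effort split", call. = FALSE)
  }
  take <- round(sizes * test_fraction)
  total_target <- round(n * test_fraction)
  residual <- total_target - sum(take)
  if (residual != 0L) {
    larger <- which.max(sizes)
    take[larger] <- max(0L, min(sizes[larger], take[larger] + residual))
  }
  test_idx <- sort(unlist(Map(function(idx, k) {
    if (k <= 0L) integer(0)
    else idx[sample.int(length(idx), min(k, length(idx)))]
  }, strata, take), use.names = FALSE))
  train_idx <- setdiff(seq_len(n), test_idx)
  list(
    train = subset_dataset(data, train_idx),
    test = if (length(test_idx)) subset_dataset(data, test_idx) else NULL,
    train_idx = train_idx, test_idx = test_idx
  )
}
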