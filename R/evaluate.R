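#' Summarize a predicted risk group
#'
#' Computes the evaluation statistics reported for each predicted group: its
#' size, its median survival time (undefined when the group's curve never
#' reaches 0.5, typical under heavy censoring) and its survival rate at the
#' horizon.
#'
#' @param data A `survival_dataset`.
#' @param idx Integer or logical index selecting the group's subjects.
#' @param t_n Evaluation horizon.
#' @param label Optional label stored with the summary.
#' @return A one-row data frame: `label`, `size`, `median_survival`,
#'   `end_survival` (all `NA` except size 0 for an empty group).
#' @export
group_summary <- function(data, idx, t_n, label = NA_character_) {
  if (is.logical(idx)) idx <- which(idx)
  if (length(idx) == 0L) {
    return(data.frame(label = label, size = 0L,
                      median_survival = NA_real_, end_survival = NA_real_))
  }
  curve <- km_estimate(subset_dataset(data, idx))
  data.frame(
    label = label,
    size = length(idx),
    median_survival = median_survival_time(curve),
    end_survival = end_survival_rate(curve, t_n)
  )
}

#' Cut a prognostic index into three risk groups
#'
#' The group-size-matching protocol used to compare an index-based model
#' (e.g. a Cox linear predictor, higher = higher risk) against a direct
#' grouping: on the reference data, the `n_high` largest index values become
#' the high-risk group and the `n_low` smallest the low-risk group, everyone
#' else intermediate. The learned cut values can then be applied to new data
#' with [apply_index_cuts()]; there the group sizes may deviate, exactly as
#' they do between training and test tables.
#'
#' Ties straddling a cut are broken by stable input order (earlier rows win
#' the more extreme group), so comparator results are reproducible.
#'
#' @param index_values Numeric prognostic index, one per subject.
#' @param n_high,n_low Target group sizes; `n_high + n_low` may not exceed
#'   the number of subjects.
#' @return A factor of labels (`high`, `intermediate`, `low`) with attribute
#'   `cuts`: the learned `low` and `high` cut values (`-Inf`/`Inf` when the
#'   respective group is empty).
#' @export
index_to_groups <- function(index_values, n_high, n_low) {
  n <- length(index_values)
  if (n_high + n_low > n) {
    stop("index_to_groups: n_high + n_low exceeds the number of subjects",
         call. = FALSE)
  }
  # stable: order() breaks ties by position, in both directions
  label <- rep("intermediate", n)
  low_idx <- if (n_low > 0) order(index_values)[seq_len(n_low)] else integer(0)
  high_idx <- if (n_high > 0) order(-index_values)[seq_len(n_high)] else integer(0)
  label[low_idx] <- "low"
  label[high_idx] <- "high"
  cuts <- c(
    low = if (n_low > 0) max(index_values[low_idx]) else -Inf,
    high = if (n_high > 0) min(index_values[high_idx]) else Inf
  )
  structure(factor(label, levels = c("high", "intermediate", "low")),
            cuts = cuts)
}

#' Apply learned index cuts to new data
#'
#' @param index_values Numeric prognostic index on the new data.
#' @param cuts The `cuts` attribute of an [index_to_groups()] result.
#' @return A factor of labels (`high`, `intermediate`, `low`).
#' @export
apply_index_cuts <- function(index_values, cuts) {
  label <- rep("intermediate", length(index_values))
  label[index_values <= cuts[["low"]]] <- "low"
  label[index_values >= cuts[["high"]]] <- "high"
  factor(label, levels = c("high", "intermediate", "low"))
}

# Censoring-stratified fold assignment: within each event stratum subjects
# are dealt round-robin into folds after shuffling.
stratified_folds <- function(events, folds) {
  assign <- integer(length(events))
  for (stratum in unique(events)) {
    idx <- which(events == stratum)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of a risk-grouping model
#'
#' Runs `folds`-fold cross-validation `repeats` times (folds stratified on
#' censoring). For every repeat and fold the model is built on the in-fold
#' training data and its predicted groups on the held-out fold are summarized.
#' The evaluation horizon of a fold is the maximum follow-up time in that
#' fold, so end-survival rates are comparable across models within a fold.
#'
#' @param data A `survival_dataset` with covariates (raw scale; the factory
#'   receives it as-is and owns any preprocessing).
#' @param model_factory Function taking a training `survival_dataset` and
#'   returning a prediction function: validation `survival_dataset` -> factor
#'   of labels (`high`, `intermediate`, `low`).
#' @param folds Number of folds (default 3).
#' @param repeats Number of repetitions (default 10).
#' @param seed RNG seed for the fold assignments and any model randomness.
#' @return A list of two data frames: `groups` with one row per
#'   repeat x fold x label (`size`, `median_survival`, `end_survival`) and
#'   `differences` with one row per repeat x fold (`end_survival_diff` =
#'   low minus high; negative flags crossing curves; `NA` when either group
#'   is empty).
#' @export
cross_validate <- function(data, model_factory, folds = 3L, repeats = 10L,
                           seed = 1L) {
  stopifnot(inherits(data, "survival_dataset"))
  if (length(data$times) < 2L * folds) {
    stop("cross_validate: dataset too small for the requested folds",
         call. = FALSE)
  }
  set.seed(seed)
  group_rows <- list()
  diff_rows <- list()
  for (r in seq_len(repeats)) {
    fold_of <- stratified_folds(data$events, folds)
    for (f in seq_len(folds)) {
      train <- subset_dataset(data, fold_of != f)
      valid <- subset_dataset(data, fold_of == f)
      predictor <- model_factory(train)
      labels <- predictor(valid)
      t_n <- max(valid$times)
      per_label <- lapply(c("high", "intermediate", "low"), function(lbl) {
        cbind(data.frame(rep = r, fold = f),
              group_summary(valid, labels == lbl, t_n, lbl))
      })
      group_rows[[length(group_rows) + 1L]] <- do.call(rbind, per_label)
      low_s <- per_label[[3L]]$end_survival
      high_s <- per_label[[1L]]$end_survival
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        rep = r, fold = f,
        end_survival_diff = low_s - high_s
      )
    }
  }
  list(
    groups = do.call(rbind, group_rows),
    differences = do.call(rbind, diff_rows)
  )
}
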