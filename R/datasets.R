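#' Load one of the five public benchmark datasets
#'
#' Convenience loaders for the publicly available survival tables shipped with
#' the `survival` package, restricted to the subjects and features used for
#' risk-group benchmarking:
#'
#' * `colon` — adjuvant chemotherapy trial; recurrence records only
#'   (929 subjects, 50% censored); time is days until recurrence.
#' * `flchain` — serum free light chain cohort, subjects with positive
#'   follow-up (7871 subjects, 72% censored); time is days until death.
#' * `nwtco` — National Wilms Tumor study (4028 subjects, 86% censored);
#'   time is days to relapse.
#' * `pbc` — the 312 randomized subjects of the primary biliary cirrhosis
#'   trial (60% censored; transplant counts as censoring for death);
#'   time is days until death.
#' * `lung` — advanced lung cancer cohort (228 subjects, 28% censored);
#'   time is survival in days.
#'
#' Each loader returns the raw covariate table (missing values intact — run
#' it through [preprocess_fit()]) together with a default declaration of
#' which columns to binarize; override it as needed.
#'
#' @param name One of `"colon"`, `"flchain"`, `"nwtco"`, `"pbc"`, `"lung"`.
#' @return A list with `data` (a `survival_dataset`), `covariates` (data
#'   frame) and `categorical_columns` (character vector, overridable).
#' @export
load_public_dataset <- function(name = c("colon", "flchain", "nwtco", "pbc",
                                         "lung")) {
  name <- match.arg(name)
  if (!requireNamespace("survival", quietly = TRUE)) {
    stop("load_public_dataset requires the 'survival' package", call. = FALSE)
  }
  get_data <- function(nm) getExportedValue("survival", nm)
  switch(
    name,
    colon = {
      df <- get_data("colon")
      df <- df[df$etype == 1, ]
      covs <- df[, c("rx", "sex", "age", "obstruct", "perfor", "adhere",
                     "nodes", "differ", "extent", "surg", "node4")]
      list(data = survival_dataset(df$time, df$status),
           covariates = covs, categorical_columns = c("rx", "differ", "extent"))
    },
    flchain = {
      df <- get_data("flchain")
      df <- df[df$futime > 0, ]
      covs <- data.frame(
        age = df$age, sex = as.character(df$sex), kappa = df$kappa,
        lambda = df$lambda, flc.grp = df$flc.grp, creatinine = df$creatinine,
        mgus = df$mgus
      )
      list(data = survival_dataset(df$futime, df$death),
           covariates = covs, categorical_columns = "sex")
    },
    nwtco = {
      df <- get_data("nwtco")
      covs <- df[, c("instit", "histol", "age", "stage")]
      list(data = survival_dataset(df$edrel, df$rel),
           covariates = covs, categorical_columns = "stage")
    },
    pbc = {
      df <- get_data("pbc")
      df <- df[seq_len(312), ]  # the randomized subjects
      covs <- df[, c("trt", "age", "sex", "ascites", "hepato", "spiders",
                     "edema", "bili", "chol", "albumin", "copper", "alk.phos",
                     "ast", "trig", "platelet", "protime", "stage")]
      covs$sex <- as.character(covs$sex)
      list(data = survival_dataset(df$time, as.numeric(df$status == 2)),
           covariates = covs,
           categorical_columns = c("sex", "edema", "stage"))
    },
    lung = {
      df <- get_data("lung")
      covs <- df[, c("age", "sex", "ph.ecog", "ph.karno", "pat.karno",
                     "meal.cal", "wt.loss")]
      list(data = survival_dataset(df$time, as.numeric(df$status == 2)),
           covariates = covs, categorical_columns = character(0))
    }
  )
}
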