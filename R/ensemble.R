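#' Ensemble configuration
#'
#' An ensemble holds an even number of membership classifiers, half trained to
#' find a high-risk group (minimizing the survival area) and half a low-risk
#' group (maximizing it). Each half must have an odd member count so that the
#' within-half "in group vs not" vote can never tie.
#'
#' @param size Total ensemble size (default 34, i.e. 17 + 17). Must be even
#'   with `size / 2` odd.
#' @param m_high,m_low Minimum group sizes for the high- and low-risk
#'   classifiers. Typically set to the group sizes a reference grouping (e.g.
#'   a recursive-partitioning tree, or quartiles) produced on the training
#'   data, so that the models are comparable.
#' @param bagging If `TRUE` (default) every member trains on its own bootstrap
#'   resample of the training data, diversifying the ensemble.
#' @param ga A `ga_config` shared by all members (each member gets its own
#'   derived seed).
#' @param n_hidden Hidden-layer width of every member (default 4).
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(size = 34L, m_high, m_low, bagging = TRUE,
                            ga = ga_config(), n_hidden = 4L) {
  size <- as.integer(size)
  if (size < 2L || size %% 2L != 0L || (size %/% 2L) %% 2L != 1L) {
    stop("ensemble_config: size must be even with an odd half (e.g. 2, 6, 34)",
         call. = FALSE)
  }
  if (m_high < 1 || m_low < 1) {
    stop("ensemble_config: minimum group sizes must be positive", call. = FALSE)
  }
  stopifnot(inherits(ga, "ga_config"))
  structure(
    list(size = size, m_high = as.integer(m_high), m_low = as.integer(m_low),
         bagging = isTRUE(bagging), ga = ga, n_hidden = as.integer(n_hidden)),
    class = "ensemble_config"
  )
}

#' Bootstrap resample of a dataset
#'
#' Draws `n` subjects with replacement from an `n`-subject dataset; the
#' bagging step that diversifies ensemble members.
#'
#' @param data A `survival_dataset`.
#' @return A `survival_dataset` of the same size.
#' @export
bag_sample <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  n <- length(data$times)
  subset_dataset(data, sample.int(n, n, replace = TRUE))
}

# Per-member seeds derived once from the master seed, so members are
# reproducible and mutually independent.
derive_member_seeds <- function(master_seed, size) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, size)
}

#' Train a risk ensemble
#'
#' Runs `size / 2` genetic-training runs in minimize mode (high-risk members)
#' and `size / 2` in maximize mode (low-risk members). The area horizon `t_n`
#' is fixed to the maximum follow-up time of `data` and shared by all members
#' so their scores refer to a common scale; with bagging on, each member's
#' fitness is evaluated on its own bootstrap resample.
#'
#' @param data A preprocessed `survival_dataset` with covariates.
#' @param config An `ensemble_config`.
#' @param seed Master seed; every member's bag and GA run derive from it.
#' @return An object of class `risk_ensemble`: lists `high` and `low` of
#'   trained genomes, the shared `arch`, `config`, `t_n`, `seed`, per-member
#'   `fitness` values and GA `logs`, and a `preprocess` slot (filled by the
#'   pipeline wrappers) holding the preprocessing parameters.
#' @export
train_ensemble <- function(data, config, seed = 1L) {
  stopifnot(inherits(data, "survival_dataset"), inherits(config, "ensemble_config"))
  if (is.null(data$covariates)) {
    stop("train_ensemble: dataset has no covariates", call. = FALSE)
  }
  n <- length(data$times)
  if (config$m_high >= n || config$m_low >= n) {
    stop("train_ensemble: minimum group sizes must be smaller than the dataset",
         call. = FALSE)
  }
  arch <- mlp_architecture(ncol(data$covariates), config$n_hidden)
  t_n <- max(data$times)
  k <- config$size %/% 2L
  seeds <- derive_member_seeds(seed, config$size)

  train_member <- function(mode, m, member_seed) {
    set.seed(member_seed)
    member_data <- if (config$bagging) bag_sample(data) else data
    ga <- config$ga
    ga$seed <- NULL  # RNG already seeded per member
    ga_train(member_data, fitness_spec(mode, m, t_n), arch, ga)
  }

  high <- lapply(seq_len(k), function(i) {
    train_member("minimize", config$m_high, seeds[i])
  })
  low <- lapply(seq_len(k), function(i) {
    train_member("maximize", config$m_low, seeds[k + i])
  })

  structure(
    list(
      high = lapply(high, `[[`, "weights"),
      low = lapply(low, `[[`, "weights"),
      fitness = list(high = vapply(high, `[[`, numeric(1), "fitness"),
                     low = vapply(low, `[[`, numeric(1), "fitness")),
      logs = list(high = lapply(high, `[[`, "log"),
                  low = lapply(low, `[[`, "log")),
      arch = arch, config = config, t_n = t_n, seed = seed,
      preprocess = NULL
    ),
    class = "risk_ensemble"
  )
}

#' @export
print.risk_ensemble <- function(x, ...) {
  cat(sprintf(
    "<risk_ensemble> %d members (%d high + %d low), %d inputs, %d hidden, t_n = %.4g\n",
    x$config$size, length(x$high), length(x$low), x$arch$n_inputs,
    x$arch$n_hidden, x$t_n
  ))
  invisible(x)
}

#' Combine subgroup votes into a risk label
#'
#' A risk label is awarded only when its own half of the ensemble votes the
#' subject in by a within-half majority (more than `k / 2` of `k` members);
#' when both halves reach a majority the one with more votes wins, and an
#' exact tie — or no majority on either side — yields "intermediate".
#'
#' @param votes_high,votes_low Integer vectors: per-subject counts of high-
#'   and low-half members voting the subject into their group.
#' @param k Members per half.
#' @return A factor with levels `high`, `intermediate`, `low`.
#' @export
vote_label <- function(votes_high, votes_low, k) {
  high_maj <- votes_high > k / 2
  low_maj <- votes_low > k / 2
  label <- rep("intermediate", length(votes_high))
  label[high_maj & (!low_maj | votes_high > votes_low)] <- "high"
  label[low_maj & (!high_maj | votes_low > votes_high)] <- "low"
  factor(label, levels = c("high", "intermediate", "low"))
}

#' Predict risk groups for new subjects
#'
#' Every member casts a binary "in my group" vote for each subject; the two
#' vote counts are combined by [vote_label()] into one of the three risk
#' groups. `newdata` must be on the scale the ensemble was trained on — if
#' the ensemble carries preprocessing parameters the raw table should be run
#' through [preprocess_apply()] first (the file-level pipeline does this).
#'
#' @param object A `risk_ensemble`.
#' @param newdata Numeric covariate matrix, columns matching the training
#'   covariates.
#' @param ... Unused.
#' @return A data frame with columns `votes_high`, `votes_low` and `label`.
#' @export
predict.risk_ensemble <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$arch$n_inputs) {
    stop(sprintf("predict: newdata has %d columns, ensemble expects %d",
                 ncol(x), object$arch$n_inputs), call. = FALSE)
  }
  count_votes <- function(members) {
    v <- integer(nrow(x))
    for (w in members) v <- v + classify_genome(w, object$arch, x)$mask
    v
  }
  votes_high <- count_votes(object$high)
  votes_low <- count_votes(object$low)
  data.frame(
    votes_high = votes_high,
    votes_low = votes_low,
    label = vote_label(votes_high, votes_low, length(object$high))
  )
}

#' Save an ensemble to a directory
#'
#' Writes a JSON manifest (configuration, seed, horizon, preprocessing
#' parameters) plus one plain-text genome file per member.
#'
#' @param ensemble A `risk_ensemble`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "risk_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- ensemble$config
  manifest <- list(
    size = cfg$size, m_high = cfg$m_high, m_low = cfg$m_low,
    bagging = cfg$bagging, n_hidden = cfg$n_hidden,
    ga = cfg$ga[c("n_pop", "p_crossover", "p_mutation", "mutation_sd",
                  "n_generations")],
    n_inputs = ensemble$arch$n_inputs,
    t_n = ensemble$t_n, seed = ensemble$seed,
    fitness = ensemble$fitness,
    preprocess = if (is.null(ensemble$preprocess)) NULL else
      serialize_preprocess(ensemble$preprocess)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(ensemble$high)) {
    write_genome(ensemble$high[[i]], ensemble$arch,
                 file.path(dir, sprintf("high_%02d.genome", i)))
  }
  for (i in seq_along(ensemble$low)) {
    write_genome(ensemble$low[[i]], ensemble$arch,
                 file.path(dir, sprintf("low_%02d.genome", i)))
  }
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#'
#' @param dir Directory containing `manifest.json` and the genome files.
#' @return A `risk_ensemble` (GA logs are not persisted).
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ga <- do.call(ga_config, manifest$ga)
  cfg <- ensemble_config(manifest$size, manifest$m_high, manifest$m_low,
                         manifest$bagging, ga, manifest$n_hidden)
  k <- manifest$size %/% 2L
  read_members <- function(prefix) {
    lapply(seq_len(k), function(i) {
      read_genome(file.path(dir, sprintf("%s_%02d.genome", prefix, i)))$weights
    })
  }
  pp <- manifest$preprocess
  structure(
    list(
      high = read_members("high"), low = read_members("low"),
      fitness = manifest$fitness, logs = NULL,
      arch = mlp_architecture(manifest$n_inputs, manifest$n_hidden),
      config = cfg, t_n = manifest$t_n, seed = manifest$seed,
      preprocess = if (is.null(pp)) NULL else deserialize_preprocess(pp)
    ),
    class = "risk_ensemble"
  )
}
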