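#' Genetic algorithm configuration
#'
#' Parameters of the steady-state genetic algorithm that evolves perceptron
#' weight vectors against the area fitness. Defaults are the values used for
#' full-scale training; the examples and vignette use smaller settings.
#'
#' @param n_pop Population size N_P (default 200; at least 4).
#' @param p_crossover Probability P_C that a selected pair undergoes two-point
#'   crossover rather than cloning (default 0.75).
#' @param p_mutation Per-weight mutation probability P_M (default 0.5).
#' @param mutation_sd Standard deviation of the zero-mean Gaussian mutation
#'   step added to a weight (default 1.5).
#' @param n_generations Number of generations N_G (default 1000); one
#'   generation has elapsed when N_P children have been born.
#' @param seed Optional RNG seed for a reproducible run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(n_pop = 200L, p_crossover = 0.75, p_mutation = 0.5,
                      mutation_sd = 1.5, n_generations = 1000L, seed = NULL) {
  if (n_pop < 4L) stop("ga_config: n_pop must be at least 4", call. = FALSE)
  if (p_crossover < 0 || p_crossover > 1 || p_mutation < 0 || p_mutation > 1) {
    stop("ga_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (mutation_sd <= 0) stop("ga_config: mutation_sd must be positive", call. = FALSE)
  if (n_generations < 0) stop("ga_config: n_generations must be >= 0", call. = FALSE)
  structure(
    list(n_pop = as.integer(n_pop), p_crossover = p_crossover,
         p_mutation = p_mutation, mutation_sd = mutation_sd,
         n_generations = as.integer(n_generations), seed = seed),
    class = "ga_config"
  )
}

#' Initialize a GA population
#'
#' Draws `n_pop` genomes with independent standard-normal weights (a scale
#' matched to z-normalized inputs) and evaluates all fitnesses.
#'
#' @param arch An `mlp_architecture`.
#' @param config A `ga_config`. If `config$seed` is set, the RNG is seeded.
#' @param fitness_fn Function mapping a genome (numeric vector) to a scalar
#'   fitness.
#' @return A `ga_state`: population matrix (one genome per row), fitness
#'   vector, `birth` order ids (cull tie-break: older first), `best_ever`
#'   genome/fitness, and a `children_born` counter.
#' @export
ga_initialize <- function(arch, config, fitness_fn) {
  stopifnot(inherits(arch, "mlp_architecture"), inherits(config, "ga_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  np <- config$n_pop
  pop <- matrix(stats::rnorm(np * arch$genome_length), nrow = np)
  fit <- apply(pop, 1L, fitness_fn)
  best <- which.max(fit)
  structure(
    list(
      population = pop, fitness = fit, birth = seq_len(np),
      best_ever = pop[best, ], best_fitness = fit[best],
      children_born = 0L, next_birth = np + 1L
    ),
    class = "ga_state"
  )
}

#' Tournament selection
#'
#' Picks two population members uniformly at random (with replacement) and
#' returns the index of the fitter one; the earlier pick wins a fitness tie.
#'
#' @param state A `ga_state`.
#' @return The selected row index into `state$population`.
#' @export
tournament_select <- function(state) {
  n <- nrow(state$population)
  i <- sample.int(n, 1L)
  j <- sample.int(n, 1L)
  if (state$fitness[j] > state$fitness[i]) j else i
}

#' Two-point crossover
#'
#' With probability `1 - p_crossover` the children are exact clones of the
#' parents. Otherwise two cut positions are drawn uniformly from the
#' `length + 1` boundary positions and the contiguous segment between them is
#' exchanged; equal cuts yield clones. At every genome position the multiset
#' of the two children's values equals that of the parents.
#'
#' @param parent_a,parent_b Numeric genomes of equal length.
#' @param p_crossover Crossover probability P_C.
#' @return A list of two child genomes.
#' @export
crossover_two_point <- function(parent_a, parent_b, p_crossover) {
  if (length(parent_a) != length(parent_b)) {
    stop("crossover_two_point: parents must have equal genome length",
         call. = FALSE)
  }
  child_a <- parent_a
  child_b <- parent_b
  if (stats::runif(1L) < p_crossover) {
    cuts <- sort(sample.int(length(parent_a) + 1L, 2L, replace = TRUE) - 1L)
    if (cuts[2L] > cuts[1L]) {
      seg <- (cuts[1L] + 1L):cuts[2L]
      child_a[seg] <- parent_b[seg]
      child_b[seg] <- parent_a[seg]
    }
  }
  list(child_a, child_b)
}

#' Gaussian mutation
#'
#' Each weight is independently perturbed with probability `p_mutation` by a
#' zero-mean Gaussian step of standard deviation `mutation_sd`; unperturbed
#' weights are returned bit-identical.
#'
#' @param genome Numeric genome.
#' @param p_mutation Per-weight mutation probability P_M.
#' @param mutation_sd Mutation step standard deviation M_std.
#' @return The mutated genome.
#' @export
mutate_gaussian <- function(genome, p_mutation, mutation_sd) {
  hit <- stats::runif(length(genome)) < p_mutation
  nh <- sum(hit)
  if (nh > 0L) genome[hit] <- genome[hit] + stats::rnorm(nh, sd = mutation_sd)
  genome
}

#' Insert children and cull the two worst
#'
#' Parents stay in the population (selection never removes them); the two
#' children join it and the two lowest-fitness members of the enlarged pool
#' are discarded, restoring the population size. Fitness ties are broken by
#' age: older members are discarded first. The best-ever record and the
#' children-born counter are updated.
#'
#' @param state A `ga_state`.
#' @param children List of two genomes.
#' @param child_fitness Numeric vector of their two fitnesses.
#' @return The updated `ga_state`.
#' @export
insert_and_cull <- function(state, children, child_fitness) {
  pop <- rbind(state$population, children[[1L]], children[[2L]])
  fit <- c(state$fitness, child_fitness)
  birth <- c(state$birth, state$next_birth, state$next_birth + 1L)
  drop_idx <- order(fit, birth)[1:2]
  keep <- setdiff(seq_along(fit), drop_idx)
  state$population <- pop[keep, , drop = FALSE]
  state$fitness <- fit[keep]
  state$birth <- birth[keep]
  state$children_born <- state$children_born + 2L
  state$next_birth <- state$next_birth + 2L
  best_child <- which.max(child_fitness)
  if (child_fitness[best_child] > state$best_fitness) {
    state$best_fitness <- child_fitness[best_child]
    state$best_ever <- children[[best_child]]
  }
  state
}

#' Train one membership classifier by genetic search
#'
#' The full training loop: initialize a random population, then repeat
#' select-crossover-mutate-insert cycles (two children per cycle) until
#' `n_generations * n_pop` children have been born. The result is the single
#' genome with the best fitness observed at any point during the run, not
#' merely the best survivor.
#'
#' @param data A preprocessed `survival_dataset` with covariates (the sample
#'   the fitness is evaluated on — under bagging, the bootstrap resample).
#' @param spec A `fitness_spec`; `spec$m` must be smaller than the dataset.
#' @param arch An `mlp_architecture` with `n_inputs` matching the covariates.
#' @param config A `ga_config`.
#' @return An object of class `ga_fit`: `weights` (the best genome),
#'   `fitness`, `arch`, `spec`, and `log` — a per-generation data frame with
#'   columns `generation`, `best_fitness`, `mean_fitness`, `best_group_size`.
#' @export
ga_train <- function(data, spec, arch, config) {
  stopifnot(inherits(data, "survival_dataset"), inherits(spec, "fitness_spec"),
            inherits(arch, "mlp_architecture"), inherits(config, "ga_config"))
  if (is.null(data$covariates)) {
    stop("ga_train: dataset has no covariates", call. = FALSE)
  }
  if (ncol(data$covariates) != arch$n_inputs) {
    stop("ga_train: covariate count does not match the architecture",
         call. = FALSE)
  }
  if (spec$m >= length(data$times)) {
    stop("ga_train: minimum group size m must be smaller than the dataset",
         call. = FALSE)
  }

  x <- data$covariates
  nh <- arch$n_hidden
  ni <- arch$n_inputs
  area_fn <- make_fitness_evaluator(data, spec)
  hid_len <- (ni + 1L) * nh
  fitness_fn <- function(w) {
    w_hidden <- matrix(w[seq_len(hid_len)], nrow = ni + 1L)
    params <- list(
      w_hidden = w_hidden[seq_len(ni), , drop = FALSE],
      b_hidden = w_hidden[ni + 1L, ],
      w_out = w[hid_len + seq_len(nh)],
      b_out = w[hid_len + nh + 1L]
    )
    area_fn(mlp_member(x, params))
  }

  state <- ga_initialize(arch, config, fitness_fn)
  target_children <- config$n_generations * config$n_pop
  log_rows <- vector("list", config$n_generations)
  gen <- 0L

  while (state$children_born < target_children) {
    pa <- tournament_select(state)
    pb <- tournament_select(state)
    kids <- crossover_two_point(state$population[pa, ], state$population[pb, ],
                                config$p_crossover)
    kids[[1L]] <- mutate_gaussian(kids[[1L]], config$p_mutation, config$mutation_sd)
    kids[[2L]] <- mutate_gaussian(kids[[2L]], config$p_mutation, config$mutation_sd)
    kf <- c(fitness_fn(kids[[1L]]), fitness_fn(kids[[2L]]))
    state <- insert_and_cull(state, kids, kf)

    while (gen < state$children_born %/% config$n_pop && gen < config$n_generations) {
      gen <- gen + 1L
      best_size <- sum(classify_genome(state$best_ever, arch, x)$mask)
      log_rows[[gen]] <- data.frame(
        generation = gen,
        best_fitness = state$best_fitness,
        mean_fitness = mean(state$fitness),
        best_group_size = best_size
      )
    }
  }

  if (state$best_fitness <= 0) {
    warning("ga_train: best fitness is 0 - no candidate satisfied the minimum ",
            "group size; consider lowering m or enlarging the population",
            call. = FALSE)
  }

  structure(
    list(
      weights = state$best_ever, fitness = state$best_fitness,
      arch = arch, spec = spec,
      log = if (gen > 0L) do.call(rbind, log_rows[seq_len(gen)]) else
        data.frame(generation = integer(0), best_fitness = numeric(0),
                   mean_fitness = numeric(0), best_group_size = integer(0))
    ),
    class = "ga_fit"
  )
}

#' @export
print.ga_fit <- function(x, ...) {
  cat(sprintf("<ga_fit> mode = %s, m = %d, fitness = %.4g (t_n = %.4g)\n",
              x$spec$mode, x$spec$m, x$fitness, x$spec$t_n))
  invisible(x)
}

#' Write a GA run log to CSV
#'
#' @param fit A `ga_fit`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ga_log <- function(fit, path) {
  stopifnot(inherits(fit, "ga_fit"))
  utils::write.csv(fit$log, path, row.names = FALSE)
  invisible(path)
}
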