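# Small separable dataset: covariate sign determines prognosis. Long-lived
# subjects (x > 0) are all censored late; short-lived (x < 0) die early.
separable_data <- function(n_long = 10, n_short = 10) {
  survival_dataset(
    c(stats::runif(n_long, 8, 10), stats::runif(n_short, 0.5, 2)),
    c(rep(0, n_long), rep(1, n_short)),
    matrix(c(stats::runif(n_long, 0.5, 2), stats::runif(n_short, -2, -0.5)),
           ncol = 1, dimnames = list(NULL, "x"))
  )
}

test_that("config validation enforces the documented bounds", {
  expect_error(ga_config(n_pop = 2), "at least 4")
  expect_error(ga_config(p_crossover = 1.2), "probabilities")
  expect_error(ga_config(mutation_sd = 0), "positive")
})

test_that("initialization fills and evaluates the whole population", {
  arch <- mlp_architecture(2, 2)
  cfg <- ga_config(n_pop = 4, seed = 99, n_generations = 1)
  fit_fn <- function(w) sum(abs(w))
  s1 <- ga_initialize(arch, cfg, fit_fn)
  expect_equal(nrow(s1$population), 4)
  expect_equal(ncol(s1$population), arch$genome_length)
  expect_equal(s1$fitness, apply(s1$population, 1, fit_fn))
  expect_equal(s1$best_fitness, max(s1$fitness))
  # fixed seed: identical population on repeat
  s2 <- ga_initialize(arch, cfg, fit_fn)
  expect_identical(s1$population, s2$population)
})

test_that("tournament selection prefers the fitter pick at the exact rate", {
  arch <- mlp_architecture(1, 1)
  state <- ga_initialize(arch, ga_config(n_pop = 4, seed = 1, n_generations = 1),
                         function(w) 0)
  state$population <- state$population[1:2, , drop = FALSE]
  state$fitness <- c(5, 1)
  state$birth <- 1:2
  set.seed(42)
  wins <- sum(vapply(1:10000, function(i) tournament_select(state) == 1L,
                     logical(1)))
  # the fitter member wins 3 of the 4 equally likely ordered pairs
  expect_gt(wins / 10000, 0.73)
  expect_lt(wins / 10000, 0.77)

  state$population <- state$population[1, , drop = FALSE]
  state$fitness <- 5
  expect_equal(tournament_select(state), 1L)
})

test_that("two-point crossover swaps one contiguous segment", {
  a <- c(1, 2, 3, 4)
  b <- c(5, 6, 7, 8)

  set.seed(7)
  kids <- crossover_two_point(a, b, p_crossover = 0)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], b)

  kids <- crossover_two_point(a, a, p_crossover = 1)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)

  expect_error(crossover_two_point(a, b[1:3], 1), "equal genome length")

  # every outcome is a contiguous swap preserving the per-position multiset,
  # and the pivot pair spanning positions 2-3 occurs (children [1,6,7,4] etc.)
  seen_middle <- FALSE
  set.seed(8)
  for (i in 1:500) {
    kids <- crossover_two_point(a, b, p_crossover = 1)
    swapped <- which(kids[[1]] != a)
    if (length(swapped)) {
      expect_identical(swapped, seq(min(swapped), max(swapped)))
    }
    expect_identical(kids[[1]] + kids[[2]], a + b)  # per-position multiset
    if (identical(kids[[1]], c(1, 6, 7, 4))) {
      expect_identical(kids[[2]], c(5, 2, 3, 8))
      seen_middle <- TRUE
    }
  }
  expect_true(seen_middle)
})

test_that("gaussian mutation perturbs the binomially expected positions", {
  g <- stats::rnorm(10000)

  set.seed(9)
  expect_identical(mutate_gaussian(g, 0, 1.5), g)

  mutated <- mutate_gaussian(g, 1, 1e-12)
  expect_false(identical(mutated, g))   # every weight moved...
  expect_equal(mutated, g, tolerance = 1e-9)  # ...but only within noise

  hits <- sum(mutate_gaussian(g, 0.5, 1.5) != g)
  interval <- stats::qbinom(c(0.0005, 0.9995), 10000, 0.5)
  expect_gte(hits, interval[1])
  expect_lte(hits, interval[2])
})

test_that("insertion keeps size, culls the two worst, tracks the best", {
  arch <- mlp_architecture(1, 1)
  state <- ga_initialize(arch, ga_config(n_pop = 4, seed = 3, n_generations = 1),
                         function(w) 0)
  state$fitness <- c(4, 3, 2, 1)
  state$best_fitness <- 4

  # children both worse than the current two worst: population unchanged
  kids <- list(rep(100, 4), rep(200, 4))
  s2 <- insert_and_cull(state, kids, c(0.5, 0.2))
  expect_equal(nrow(s2$population), 4)
  expect_setequal(s2$fitness, c(4, 3, 2, 1))
  expect_equal(s2$children_born, 2L)

  # a dominant child enters and becomes best_ever
  s3 <- insert_and_cull(state, kids, c(9, 0.1))
  expect_equal(nrow(s3$population), 4)
  expect_true(9 %in% s3$fitness)
  expect_equal(s3$best_fitness, 9)
  expect_identical(s3$best_ever, kids[[1]])

  # max fitness never decreases across random insertions
  set.seed(31)
  s <- state
  for (i in 1:50) {
    prev_max <- max(s$fitness)
    s <- insert_and_cull(s, list(stats::rnorm(4), stats::rnorm(4)),
                         stats::runif(2, 0, 5))
    expect_gte(max(s$fitness), prev_max)
  }
})

test_that("fitness ties are culled oldest-first", {
  arch <- mlp_architecture(1, 1)
  state <- ga_initialize(arch, ga_config(n_pop = 4, seed = 5, n_generations = 1),
                         function(w) 0)
  state$fitness <- c(1, 1, 1, 1)
  state$best_fitness <- 1
  s2 <- insert_and_cull(state, list(rep(9, 4), rep(8, 4)), c(1, 1))
  # all six candidates tie at fitness 1: members born first (rows 1, 2) go
  expect_equal(s2$birth, c(3L, 4L, 5L, 6L))
})

test_that("training is seed-reproducible and improves monotonically", {
  set.seed(21)
  d <- separable_data()
  arch <- mlp_architecture(1, 2)
  spec <- fitness_spec("maximize", m = 5, t_n = max(d$times))
  cfg <- ga_config(n_pop = 10, n_generations = 10, seed = 77)

  f1 <- ga_train(d, spec, arch, cfg)
  f2 <- ga_train(d, spec, arch, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$fitness, f2$fitness)

  expect_equal(nrow(f1$log), 10)
  expect_true(all(diff(f1$log$best_fitness) >= 0))
  expect_gte(f1$fitness, max(f1$log$best_fitness))
  expect_gte(sum(classify_genome(f1$weights, arch, d$covariates)$mask), spec$m)
})

test_that("zero generations returns the best of the initial population", {
  set.seed(22)
  d <- separable_data()
  arch <- mlp_architecture(1, 2)
  spec <- fitness_spec("maximize", m = 1, t_n = max(d$times))
  cfg <- ga_config(n_pop = 8, n_generations = 0, seed = 13)

  fit <- ga_train(d, spec, arch, cfg)
  state <- ga_initialize(arch, ga_config(n_pop = 8, seed = 13, n_generations = 0),
                         function(w) {
                           m <- classify_genome(w, arch, d$covariates)
                           group_fitness(d, m, spec)
                         })
  expect_identical(fit$weights, state$best_ever)
  expect_identical(fit$fitness, state$best_fitness)
})

test_that("the GA recovers the separable long-lived group", {
  set.seed(23)
  d <- separable_data(n_long = 10, n_short = 10)
  arch <- mlp_architecture(1, 2)
  spec <- fitness_spec("maximize", m = 5, t_n = max(d$times))

  hits <- 0
  for (s in 1:5) {
    fit <- ga_train(d, spec, arch,
                    ga_config(n_pop = 50, n_generations = 50, seed = s))
    mask <- classify_genome(fit$weights, arch, d$covariates)$mask
    # members only among the long-lived (first 10 subjects)
    if (sum(mask) >= 5 && all(which(mask == 1) <= 10)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("an infeasible minimum group size is rejected or diagnosed", {
  set.seed(24)
  d <- separable_data(5, 5)
  arch <- mlp_architecture(1, 2)
  expect_error(
    ga_train(d, fitness_spec("maximize", 10, 10), arch, ga_config(n_pop = 4)),
    "smaller than the dataset"
  )
})
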