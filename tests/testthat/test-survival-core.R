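step_curve <- function(time, survival, n = 10L) {
  structure(list(time = time, survival = survival, n = n), class = "km_curve")
}

test_that("product-limit estimate matches hand-computed cases", {
  # no events: estimator stays at 1, no steps
  flat <- km_estimate(survival_dataset(c(1, 2, 3), c(0, 0, 0)))
  expect_length(flat$time, 0)
  expect_equal(end_survival_rate(flat, 10), 1)

  # all events: S = prod(1 - d_i/n_i) = 2/3, 1/3, 0
  full <- km_estimate(survival_dataset(c(1, 2, 3), c(1, 1, 1)))
  expect_equal(full$time, c(1, 2, 3))
  expect_equal(full$survival, c(2 / 3, 1 / 3, 0))

  # censoring at t = 2 shrinks the risk set to 1 before the last event
  mixed <- km_estimate(survival_dataset(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(mixed$time, c(1, 3))
  expect_equal(mixed$survival, c(2 / 3, 0))
})

test_that("km_estimate agrees with the survival package on random data", {
  skip_if_not_installed("survival")
  set.seed(101)
  for (i in 1:300) {
    d <- random_dataset(sample(1:30, 1), allow_ties = i %% 2 == 0)
    got <- km_estimate(d)
    ref <- survfit_curve(d)
    expect_equal(got$time, ref$time, tolerance = 0)
    expect_equal(got$survival, ref$survival, tolerance = 1e-12)
  }
})

test_that("curve invariants hold on random inputs", {
  set.seed(202)
  for (i in 1:50) {
    d <- random_dataset(sample(2:40, 1))
    crv <- km_estimate(d)
    expect_true(all(diff(crv$time) > 0))
    expect_true(all(diff(crv$survival) <= 0))
    expect_true(all(crv$survival >= 0 & crv$survival <= 1))
  }
})

test_that("area under the curve is the exact step-function integral", {
  expect_equal(area_under_curve(step_curve(numeric(0), numeric(0)), 10), 10)
  crv <- step_curve(c(1, 2), c(0.5, 0))
  expect_equal(area_under_curve(crv, 2), 1.5)
  expect_equal(area_under_curve(crv, 5), 1.5)  # zero tail adds nothing
  expect_error(area_under_curve(crv, 1.5), "last time point")
})

test_that("area matches fine-grid numerical integration on random curves", {
  set.seed(303)
  for (i in 1:30) {
    d <- random_dataset(sample(3:25, 1))
    crv <- km_estimate(d)
    t_n <- max(d$times) * stats::runif(1, 1, 1.5)
    expect_equal(
      area_under_curve(crv, t_n),
      numeric_step_area(crv$time, crv$survival, t_n),
      tolerance = 1e-4 * t_n
    )
  }
})

test_that("complement_area is the exact reflection at the horizon", {
  expect_equal(complement_area(0, 10), 10)
  expect_equal(complement_area(10, 10), 0)
  expect_equal(complement_area(1.5, 2), 0.5)
  expect_error(complement_area(11, 10), "exceeds")

  # A + A' = t_n exactly, on random curves
  set.seed(404)
  for (i in 1:50) {
    d <- random_dataset(sample(2:20, 1))
    crv <- km_estimate(d)
    t_n <- max(d$times) + stats::runif(1, 0, 3)
    a <- area_under_curve(crv, t_n)
    expect_equal(complement_area(a, t_n) + a, t_n, tolerance = 1e-12)
  }
})

test_that("group fitness enforces the minimum group size and the mode", {
  d <- survival_dataset(c(1, 2, 3, 4), c(1, 1, 1, 0))
  spec <- fitness_spec("maximize", m = 3, t_n = 4)

  # below the floor: exactly zero
  expect_identical(group_fitness(d, group_membership(c(1, 1, 0, 0)), spec), 0)

  # event-free members attain the maximum t_n
  ef <- survival_dataset(c(5, 6, 7), c(0, 0, 0))
  expect_equal(
    group_fitness(ef, group_membership(c(1, 1, 1)),
                  fitness_spec("maximize", 2, 7)),
    7
  )

  # hand-computed: A = 1 + 2/3 + 1/3 = 2, so A' = 3 - 2 = 1
  tri <- survival_dataset(c(1, 2, 3), c(1, 1, 1))
  expect_equal(
    group_fitness(tri, group_membership(c(1, 1, 1)),
                  fitness_spec("minimize", 1, 3)),
    1
  )
})

test_that("fitness is zero iff the group is under-sized (positive above)", {
  set.seed(505)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    d <- survival_dataset(stats::runif(n, 0.5, 10), stats::rbinom(n, 1, 0.6))
    t_n <- max(d$times) + 1
    m <- sample(2:n, 1)
    spec <- fitness_spec("maximize", m, t_n)
    mask <- integer(n)
    mask[sample.int(n, sample(1:n, 1))] <- 1L
    f <- group_fitness(d, group_membership(mask), spec)
    if (sum(mask) < m) expect_identical(f, 0) else expect_gt(f, 0)
  }
})

test_that("adding a late event-free subject never hurts a maximize group", {
  set.seed(606)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    times <- stats::runif(n, 1, 10)
    events <- stats::rbinom(n, 1, 0.5)
    d0 <- survival_dataset(times, events)
    d1 <- survival_dataset(c(times, max(times) + 1), c(events, 0))
    t_n <- max(times) + 2
    f0 <- group_fitness(d0, group_membership(rep(1, n)),
                        fitness_spec("maximize", 1, t_n))
    f1 <- group_fitness(d1, group_membership(rep(1, n + 1)),
                        fitness_spec("maximize", 1, t_n))
    expect_gte(f1, f0)
  }
})

test_that("the fast fitness evaluator equals group_fitness on random masks", {
  set.seed(707)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- random_dataset(n)
    t_n <- max(d$times) + stats::runif(1, 0, 2)
    mode <- sample(c("maximize", "minimize"), 1)
    spec <- fitness_spec(mode, sample(1:4, 1), t_n)
    evaluator <- survarea:::make_fitness_evaluator(d, spec)
    for (j in 1:10) {
      mask <- stats::rbinom(n, 1, 0.5)
      expect_equal(evaluator(mask == 1),
                   group_fitness(d, group_membership(mask), spec))
    }
  }
})

test_that("survival CSV round-trips through the standard dialect", {
  d <- survival_dataset(c(3, 1, 4), c(1, 0, 1),
                        matrix(1:6, ncol = 2, dimnames = list(NULL, c("a", "b"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survival_csv(d, path)
  back <- read_survival_csv(path)
  expect_equal(back$data$times, d$times)
  expect_equal(back$data$events, d$events)
  expect_equal(as.matrix(back$covariates), d$covariates)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("time,foo\n1,2", bad)
  expect_error(read_survival_csv(bad), "event")
})

test_that("dataset constructor rejects malformed inputs", {
  expect_error(survival_dataset(numeric(0), numeric(0)), "at least one")
  expect_error(survival_dataset(c(1, 2), c(1)), "equal length")
  expect_error(survival_dataset(c(-1, 2), c(1, 0)), "non-negative")
  expect_error(survival_dataset(c(1, 2), c(1, 2)), "0 .censored. or 1")
  expect_error(survival_dataset(c(1, 2), c(1, 0), matrix(1, 3, 1)), "one row")
})
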