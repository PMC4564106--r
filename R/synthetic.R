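#' Specification of a synthetic censored-survival dataset
#'
#' Describes a population of latent risk strata with proportional-hazards
#' structure: event times are Weibull with a common baseline and a per-stratum
#' hazard multiplier, censoring times are independent exponentials calibrated
#' so that a target fraction of subjects is censored. The covariates handed to
#' models are the stratum indicators plus pure-noise columns, so the true risk
#' structure is known and recoverable — the construction every training and
#' recovery test in the package rests on.
#'
#' @param n Number of subjects.
#' @param strata List of `c(proportion, hazard_multiplier)` pairs; the
#'   proportions must sum to 1 and the multipliers must be positive.
#' @param baseline_scale Weibull scale of the baseline (multiplier 1) stratum,
#'   in the time unit of the dataset (default 365, i.e. a one-year scale in
#'   days).
#' @param weibull_shape Weibull shape; 1 (default) gives exponential times.
#' @param censor_rate Target censored fraction in \[0, 1).
#' @param p_noise Number of non-informative standard-normal covariates.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n, strata = list(c(1, 1)), baseline_scale = 365,
                     weibull_shape = 1, censor_rate = 0, p_noise = 0L) {
  props <- vapply(strata, `[`, numeric(1), 1L)
  hazards <- vapply(strata, `[`, numeric(1), 2L)
  if (abs(sum(props) - 1) > 1e-8) {
    stop("sim_spec: stratum proportions must sum to 1", call. = FALSE)
  }
  if (any(hazards <= 0)) {
    stop("sim_spec: hazard multipliers must be positive", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("sim_spec: censor_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n < 1 || baseline_scale <= 0 || weibull_shape <= 0 || p_noise < 0) {
    stop("sim_spec: invalid size or scale parameters", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), proportions = props, hazards = hazards,
         baseline_scale = baseline_scale, weibull_shape = weibull_shape,
         censor_rate = censor_rate, p_noise = as.integer(p_noise)),
    class = "sim_spec"
  )
}

# P(censored) = P(C < T) for C ~ Exp(rate) independent of the Weibull mixture
# T. Exact for the exponential case; numerical integration otherwise.
censoring_probability <- function(rate, spec) {
  if (rate <= 0) return(0)
  if (spec$weibull_shape == 1) {
    lambda <- spec$hazards / spec$baseline_scale
    return(sum(spec$proportions * rate / (rate + lambda)))
  }
  # P(censored | stratum) = 1 - E[exp(-rate * T)]; integrating against the
  # event-time density keeps the quadrature stable at extreme rates
  per_stratum <- vapply(seq_along(spec$hazards), function(i) {
    h <- spec$hazards[i]
    sc <- spec$baseline_scale
    sh <- spec$weibull_shape
    dens <- function(t) {
      h * sh / sc * (t / sc)^(sh - 1) * exp(-h * (t / sc)^sh)
    }
    1 - stats::integrate(function(t) dens(t) * exp(-rate * t),
                         lower = 0, upper = Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  sum(spec$proportions * per_stratum)
}

# Solve for the exponential censoring rate hitting the target censored
# fraction; monotone in the rate, so a bracketed root always exists.
calibrate_censoring_rate <- function(spec) {
  if (spec$censor_rate == 0) return(0)
  f <- function(log_rate) {
    censoring_probability(exp(log_rate), spec) - spec$censor_rate
  }
  base_rate <- 1 / spec$baseline_scale
  lo <- log(base_rate) - 25
  hi <- log(base_rate) + 25
  if (f(lo) > 0 || f(hi) < 0) {
    stop("calibrate_censoring_rate: target censor_rate is infeasible",
         call. = FALSE)
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate a censored survival dataset with known risk strata
#'
#' Draws stratum labels from the specified proportions, event times from the
#' per-stratum Weibull, and independent exponential censoring times whose rate
#' is calibrated (analytically for exponential event times, by quadrature
#' otherwise) to the target censored fraction. The observed follow-up is the
#' minimum of the two with the usual event indicator.
#'
#' @param spec A `sim_spec`.
#' @param seed RNG seed; fixed seed gives a bit-identical dataset.
#' @return A list with `data` (a `survival_dataset` whose covariates are the
#'   stratum indicators `stratum.1 ...` plus `noise.1 ...` columns), `stratum`
#'   (the latent per-subject stratum index — never feed it to a model) and
#'   `censoring_rate` (the calibrated exponential rate).
#' @export
simulate_survival <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  n <- spec$n
  k <- length(spec$hazards)
  stratum <- sample.int(k, n, replace = TRUE, prob = spec$proportions)
  # T = scale * (E / h)^(1/shape), E ~ Exp(1)
  e <- stats::rexp(n)
  event_time <- spec$baseline_scale *
    (e / spec$hazards[stratum])^(1 / spec$weibull_shape)
  cens_rate <- calibrate_censoring_rate(spec)
  cens_time <- if (cens_rate > 0) stats::rexp(n, rate = cens_rate) else
    rep(Inf, n)
  observed <- pmin(event_time, cens_time)
  event <- as.numeric(event_time <= cens_time)

  indicators <- matrix(0, nrow = n, ncol = k,
                       dimnames = list(NULL, paste0("stratum.", seq_len(k))))
  indicators[cbind(seq_len(n), stratum)] <- 1
  covariates <- indicators
  if (spec$p_noise > 0L) {
    noise <- matrix(stats::rnorm(n * spec$p_noise), nrow = n,
                    dimnames = list(NULL, paste0("noise.", seq_len(spec$p_noise))))
    covariates <- cbind(covariates, noise)
  }

  list(
    data = survival_dataset(observed, event, covariates),
    stratum = stratum,
    censoring_rate = cens_rate
  )
}

#' Write a simulated dataset to CSV
#'
#' Emits the package's standard survival CSV (`time`, `event`, covariates)
#' plus a sidecar `<path>.strata.csv` holding the latent stratum labels.
#'
#' @param sim A result of [simulate_survival()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(sim, path) {
  write_survival_csv(sim$data, path)
  utils::write.csv(data.frame(stratum = sim$stratum),
                   paste0(path, ".strata.csv"), row.names = FALSE)
  invisible(path)
}
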