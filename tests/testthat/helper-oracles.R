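# Independent oracles the implementation is checked against. These never call
# the package's own code paths.

# Random censored sample drawn from the current RNG stream.
random_dataset <- function(n, max_time = 10, censor_prob = 0.4,
                           allow_ties = TRUE) {
  times <- if (allow_ties) sample(1:max_time, n, replace = TRUE) + 0 else
    stats::runif(n, 0.01, max_time)
  events <- stats::rbinom(n, 1, 1 - censor_prob)
  survival_dataset(times, events)
}

# Product-limit curve via the survival package: step times (distinct times
# with >= 1 event) and the survival just after each.
survfit_curve <- function(data) {
  sf <- survival::survfit(
    survival::Surv(data$times, data$events) ~ 1,
    conf.type = "none"
  )
  keep <- sf$n.event > 0
  list(time = sf$time[keep], survival = sf$surv[keep])
}

# Fine-grid rectangle integration of a step curve over [0, t_n]. The curve is
# right-continuous, S = 1 before the first step, flat after the last.
numeric_step_area <- function(step_time, step_surv, t_n, n_grid = 1e5) {
  grid <- seq(0, t_n, length.out = n_grid + 1)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  s <- vapply(mid, function(t) {
    i <- sum(step_time <= t)
    if (i == 0) 1 else step_surv[i]
  }, numeric(1))
  sum(s) * (t_n / n_grid)
}

# Brute-force fitness of a membership mask: survfit curve + rectangle area.
brute_fitness <- function(data, mask, mode, m, t_n) {
  m_size <- sum(mask)
  if (m_size < m) return(0)
  sub <- survival_dataset(data$times[mask == 1], data$events[mask == 1])
  crv <- survfit_curve(sub)
  lo <- c(0, crv$time)
  hi <- c(crv$time, t_n)
  a <- sum(c(1, crv$survival) * (hi - lo))
  if (mode == "maximize") a else t_n - a
}

# Hand-coded ensemble voting rule, written directly from its verbal
# definition: intermediate when neither half reaches a within-half majority
# or when high and low votes tie; otherwise the larger vote count wins.
vote_oracle <- function(h, l, k) {
  if (h <= k / 2 && l <= k / 2) return("intermediate")
  if (h == l) return("intermediate")
  if (h > l) "high" else "low"
}
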