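#' Kaplan-Meier estimation and the area-under-the-curve objective
#'
#' The product-limit estimator, the exact integral of its step function over a
#' fixed horizon, and the derived group-level statistics (median survival
#' time, end survival rate). The area is the quantity the genetic training
#' maximizes (low-risk groups) or minimizes (high-risk groups).
#'
#' @name km
NULL

# Product-limit steps from observations already sorted by (time, events first).
# Per-observation factors reproduce the grouped (1 - d/n) product exactly
# because events at a tied time are consecutive and processed before
# censorings. Returns step times (distinct event times) and the survival
# probability just after each.
km_steps_sorted <- function(times, events) {
  n <- length(times)
  at_risk <- n:1
  fac <- rep(1, n)
  ev <- events == 1
  fac[ev] <- (at_risk[ev] - 1) / at_risk[ev]
  surv <- cumprod(fac)
  if (!any(ev)) {
    return(list(time = numeric(0), survival = numeric(0)))
  }
  ev_idx <- which(ev)
  # last event per distinct time carries the post-tie survival value
  keep <- ev_idx[!duplicated(times[ev_idx], fromLast = TRUE)]
  list(time = times[keep], survival = surv[keep])
}

# Sort order used everywhere: ascending time, events before censorings at ties.
km_order <- function(times, events) order(times, -events)

#' Kaplan-Meier (product-limit) estimate
#'
#' Estimates the survival function of a right-censored sample. The returned
#' curve is a right-continuous step function: `survival[i]` is the survival
#' probability just after `time[i]`, with survival 1 before the first step.
#' Steps occur only at distinct times with at least one observed event; ties
#' between events and censorings at the same time are resolved by processing
#' events first (the standard convention).
#'
#' @param data A `survival_dataset` (covariates ignored).
#' @return An object of class `km_curve`: list with strictly increasing
#'   `time`, non-increasing `survival` in \[0, 1\], and `n` (sample size).
#' @export
#' @examples
#' km_estimate(survival_dataset(c(1, 2, 3), c(1, 0, 1)))
km_estimate <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  o <- km_order(data$times, data$events)
  steps <- km_steps_sorted(data$times[o], data$events[o])
  structure(
    list(time = steps$time, survival = steps$survival, n = length(data$times)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, %d steps", x$n, length(x$time)))
  if (length(x$time)) {
    cat(sprintf(", final S = %.4g at t = %.4g", x$survival[length(x$survival)],
                x$time[length(x$time)]))
  }
  cat("\n")
  invisible(x)
}

#' Area under a Kaplan-Meier curve over a fixed horizon
#'
#' Exact integral of the step function on \[0, t_N\]: survival is 1 before the
#' first step and the last segment is extended flat to `t_n`. The value lies
#' in \[0, t_N\]; a flat curve attains the maximum t_N. This is the training
#' objective for low-risk groups (the restricted mean survival time of the
#' group, up to the common horizon).
#'
#' @param curve A `km_curve`.
#' @param t_n Horizon; must be at least the curve's last step time.
#' @return The area, a value in \[0, `t_n`\].
#' @export
area_under_curve <- function(curve, t_n) {
  stopifnot(inherits(curve, "km_curve"))
  if (length(t_n) != 1L || !is.finite(t_n) || t_n <= 0) {
    stop("area_under_curve: t_n must be a single positive number", call. = FALSE)
  }
  nt <- length(curve$time)
  if (nt > 0L && t_n < curve$time[nt]) {
    stop("area_under_curve: t_n is smaller than the curve's last time point",
         call. = FALSE)
  }
  lo <- c(0, curve$time)
  hi <- c(curve$time, t_n)
  sum(c(1, curve$survival) * (hi - lo))
}

#' Complement of the area under the curve
#'
#' Because the area is bounded above by the horizon, minimizing it is
#' equivalent to maximizing `t_n - A`; this complement is the training
#' objective for high-risk groups (higher is better in both modes).
#'
#' @param a Area in \[0, `t_n`\].
#' @param t_n Horizon.
#' @return `t_n - a`.
#' @export
complement_area <- function(a, t_n) {
  if (length(a) != 1L || a < 0) {
    stop("complement_area: a must be a single non-negative number", call. = FALSE)
  }
  if (a > t_n) {
    stop("complement_area: a exceeds the horizon t_n", call. = FALSE)
  }
  t_n - a
}

#' Median survival time of a curve
#'
#' The smallest step time at which survival drops to 0.5 or below; undefined
#' (returned as `NA`) if the curve never reaches 0.5 — typical for heavily
#' censored low-risk groups.
#'
#' @param curve A `km_curve`.
#' @return The median survival time, or `NA_real_` if undefined.
#' @export
median_survival_time <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$survival <= 0.5)
  if (length(hit) == 0L) NA_real_ else curve$time[hit[1L]]
}

#' Survival probability at the horizon
#'
#' The curve's value at `t_n` with the final segment extended flat; 1 for a
#' curve with no events.
#'
#' @param curve A `km_curve`.
#' @param t_n Horizon (must be at least the last step time).
#' @return Survival probability in \[0, 1\].
#' @export
end_survival_rate <- function(curve, t_n) {
  stopifnot(inherits(curve, "km_curve"))
  nt <- length(curve$time)
  if (nt > 0L && t_n < curve$time[nt]) {
    stop("end_survival_rate: t_n is smaller than the curve's last time point",
         call. = FALSE)
  }
  if (nt == 0L) 1 else curve$survival[nt]
}

#' Low-minus-high end survival difference
#'
#' The gap between the low-risk and high-risk group survival probabilities at
#' the horizon. A negative value means the low-risk curve lies below the
#' high-risk curve at the final time point — crossing survival curves, a
#' diagnostic of misclassification.
#'
#' @param low_curve,high_curve `km_curve`s of the predicted low- and
#'   high-risk groups.
#' @param t_n Common horizon.
#' @return `end_survival_rate(low) - end_survival_rate(high)`.
#' @export
end_survival_difference <- function(low_curve, high_curve, t_n) {
  end_survival_rate(low_curve, t_n) - end_survival_rate(high_curve, t_n)
}

#' Export a curve as a two-column CSV
#'
#' Writes `time,survival` rows, including the implicit origin (0, 1).
#'
#' @param curve A `km_curve`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(
    data.frame(time = c(0, curve$time), survival = c(1, curve$survival)),
    path, row.names = FALSE
  )
  invisible(path)
}
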