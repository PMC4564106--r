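#' Group membership vector
#'
#' @param mask Binary (0/1 or logical) vector over a dataset's subjects;
#'   1 = in the candidate risk group.
#' @return An object of class `group_membership` with elements `mask`
#'   (integer 0/1) and `m_size` (number of members).
#' @export
group_membership <- function(mask) {
  mask <- as.integer(mask)
  if (anyNA(mask) || !all(mask %in% c(0L, 1L))) {
    stop("group_membership: mask must be binary", call. = FALSE)
  }
  structure(list(mask = mask, m_size = sum(mask)), class = "group_membership")
}

#' Fitness specification for the area objective
#'
#' @param mode `"maximize"` rewards a large area (low-risk groups);
#'   `"minimize"` rewards a small area via its complement (high-risk groups).
#' @param m Hard minimum group size: candidates selecting fewer than `m`
#'   subjects score zero, which blocks the degenerate optimum of a
#'   single-subject group.
#' @param t_n Horizon: the common right endpoint over which areas are
#'   compared. Fix it once per training run (the maximum follow-up time of
#'   the training data) so scores are comparable across candidate groups.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(mode = c("maximize", "minimize"), m, t_n) {
  mode <- match.arg(mode)
  if (length(m) != 1L || m < 1 || m != round(m)) {
    stop("fitness_spec: m must be a positive integer", call. = FALSE)
  }
  if (length(t_n) != 1L || !is.finite(t_n) || t_n <= 0) {
    stop("fitness_spec: t_n must be a single positive number", call. = FALSE)
  }
  structure(list(mode = mode, m = as.integer(m), t_n = as.numeric(t_n)),
            class = "fitness_spec")
}

#' Area-based fitness of a candidate risk group
#'
#' The score a candidate group earns during genetic training: zero if the
#' group has fewer than `spec$m` members, otherwise the area under the
#' Kaplan-Meier curve of the member subset (mode `"maximize"`) or its
#' complement `t_n - A` (mode `"minimize"`). Higher is always better.
#'
#' @param data A `survival_dataset`.
#' @param membership A `group_membership` aligned with `data`.
#' @param spec A `fitness_spec`.
#' @return A non-negative scalar fitness.
#' @export
group_fitness <- function(data, membership, spec) {
  stopifnot(inherits(data, "survival_dataset"),
            inherits(membership, "group_membership"),
            inherits(spec, "fitness_spec"))
  if (length(membership$mask) != length(data$times)) {
    stop("group_fitness: membership mask does not match dataset size",
         call. = FALSE)
  }
  if (membership$m_size < spec$m) return(0)
  sel <- membership$mask == 1L
  curve <- km_estimate(subset_dataset(data, sel))
  a <- area_under_curve(curve, spec$t_n)
  if (spec$mode == "maximize") a else complement_area(a, spec$t_n)
}

# Fast fitness evaluator used inside the GA inner loop. Pre-sorts the dataset
# once; each call takes a logical membership vector in *original* subject
# order and computes the subgroup KM area without re-sorting. Identical in
# value to group_fitness(); kept separate because it runs O(10^5) times per
# training run.
make_fitness_evaluator <- function(data, spec) {
  o <- km_order(data$times, data$events)
  ts <- data$times[o]
  es <- data$events[o] == 1
  t_n <- spec$t_n
  m_min <- spec$m
  minimize <- spec$mode == "minimize"
  if (any(ts > t_n)) {
    stop("fitness evaluator: follow-up times exceed the horizon t_n", call. = FALSE)
  }

  function(in_group) {
    sel <- in_group[o]
    m_size <- sum(sel)
    if (m_size < m_min) return(0)
    t <- ts[sel]
    e <- es[sel]
    at_risk <- m_size:1
    fac <- rep.int(1, m_size)
    fac[e] <- (at_risk[e] - 1) / at_risk[e]
    if (any(e)) {
      surv <- cumprod(fac)
      ev_idx <- which(e)
      keep <- ev_idx[!duplicated(t[ev_idx], fromLast = TRUE)]
      st <- t[keep]
      ss <- surv[keep]
      a <- sum(c(1, ss) * (c(st, t_n) - c(0, st)))
    } else {
      a <- t_n
    }
    if (minimize) t_n - a else a
  }
}
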