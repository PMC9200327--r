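#' Bray-Curtis dissimilarity between two community states
#'
#' \deqn{BC = \frac{\sum_i |X_{i,1} - X_{i,2}|}{\sum_i (X_{i,1} + X_{i,2})}}
#' computed on absolute abundances.  Symmetric, bounded in \[0, 1\], zero
#' iff the states are identical and one iff their supports are disjoint.
#'
#' @param x1,x2 non-negative abundance vectors of equal length (not both
#'   all-zero).
#' @return dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(6, 2), c(2, 2))  # 1/3
#' @export
bray_curtis <- function(x1, x2) {
  x1 <- as.numeric(x1)
  x2 <- as.numeric(x2)
  if (length(x1) != length(x2)) stop("states must have equal length")
  if (any(x1 < 0) || any(x2 < 0)) stop("abundances must be non-negative")
  tot <- sum(x1 + x2)
  if (tot == 0) stop("undefined-dissimilarity: both states are all-zero")
  sum(abs(x1 - x2)) / tot
}

#' Relative abundances (optionally summed by group)
#'
#' @param state non-negative abundance vector with positive total.
#' @param groups optional [group_structure()]; if given, abundances are
#'   summed per group before normalization.
#' @return vector on the simplex (sums to 1), named by species index or
#'   group label.
#' @export
relative_abundances <- function(state, groups = NULL) {
  x <- as.numeric(state)
  if (any(x < 0)) stop("abundances must be non-negative")
  tot <- sum(x)
  if (tot == 0) stop("undefined-composition: total abundance is zero")
  if (is.null(groups)) {
    out <- x / tot
    names(out) <- paste0("X_", seq_along(x))
    return(out)
  }
  stopifnot(inherits(groups, "fracomm_groups"))
  sums <- vapply(groups$members, function(m) sum(x[m]), numeric(1))
  sums / tot
}

#' Dominant group (or species) of a community state
#'
#' @inheritParams relative_abundances
#' @return label of the group with the largest summed relative abundance
#'   (species name when `groups` is `NULL`).  An exact tie is an error
#'   (`ambiguous-dominance`): ties are measure-zero and indicate a
#'   degenerate setup.
#' @export
dominant_group <- function(state, groups = NULL) {
  rel <- relative_abundances(state, groups)
  top <- which(rel == max(rel))
  if (length(top) > 1L) {
    stop("ambiguous-dominance: exact tie between ",
         paste(names(rel)[top], collapse = ", "))
  }
  names(rel)[top]
}

#' Convergence specification
#'
#' Defines when a trajectory counts as having converged to a reference
#' state: the Bray-Curtis dissimilarity to `reference` must drop to
#' `threshold` or below (the "convergence interval") and stay there for
#' `dwell` time units.
#'
#' @param reference non-negative reference state (typically a stable fixed
#'   point).
#' @param threshold Bray-Curtis threshold in (0, 1).
#' @param dwell required dwell time >= 0 (default 0 = first crossing).
#' @return An object of class `fracomm_convergence_spec`.
#' @export
convergence_spec <- function(reference, threshold, dwell = 0) {
  reference <- as.numeric(reference)
  if (any(reference < 0)) stop("reference must be non-negative")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0, 1)")
  }
  if (!is.finite(dwell) || dwell < 0) stop("dwell must be >= 0")
  structure(list(reference = reference, threshold = threshold,
                 dwell = dwell),
            class = "fracomm_convergence_spec")
}

#' Time of convergence to a reference state
#'
#' Earliest grid time `t*` at which the Bray-Curtis dissimilarity between
#' the trajectory and the reference is at or below the threshold for all
#' grid times in `[t*, t* + dwell]`.  Returns `NA` ("absent") if the
#' trajectory never converges within its horizon -- explicitly
#' distinguishable from a numeric `t*` equal to the horizon.
#'
#' @param traj a `fracomm_trajectory`.
#' @param spec a [convergence_spec()].
#' @return numeric time, or `NA_real_` if convergence is not achieved.
#' @export
convergence_time <- function(traj, spec) {
  stopifnot(inherits(traj, "fracomm_trajectory"),
            inherits(spec, "fracomm_convergence_spec"))
  bc <- trajectory_bc(traj, spec$reference)
  inside <- bc <= spec$threshold
  if (!any(inside)) return(NA_real_)
  if (spec$dwell == 0) return(traj$times[which(inside)[1L]])
  tt <- traj$times
  n <- length(tt)
  for (i in which(inside)) {
    jmax <- which(tt <= tt[i] + spec$dwell + 1e-12)
    jmax <- jmax[length(jmax)]
    if (tt[jmax] < tt[i] + spec$dwell - 1e-12) return(NA_real_) # horizon cut
    if (all(inside[i:jmax])) return(tt[i])
  }
  NA_real_
}

trajectory_bc <- function(traj, reference) {
  num <- colSums(abs(traj$states - reference))
  den <- colSums(traj$states + reference)
  if (any(den == 0)) {
    stop("undefined-dissimilarity: all-zero state against all-zero reference")
  }
  num / den
}

#' Recovery time after a perturbation
#'
#' [convergence_time()] applied to the part of the trajectory at or after
#' `perturbation_end_time`, reported relative to that time: how long after
#' the perturbation ends the community re-enters (and, given a dwell,
#' stays in) the convergence interval around its initial stable state.
#'
#' @param traj a `fracomm_trajectory`.
#' @param spec a [convergence_spec()] whose reference is the pre-perturbation
#'   stable state.
#' @param perturbation_end_time time at which the perturbation ends; must
#'   lie within the trajectory range.
#' @return recovery time (>= 0), or `NA_real_` if the community does not
#'   recover within the horizon.
#' @export
recovery_time <- function(traj, spec, perturbation_end_time) {
  stopifnot(inherits(traj, "fracomm_trajectory"))
  tt <- traj$times
  if (perturbation_end_time < tt[1L] - 1e-9 ||
      perturbation_end_time > tt[length(tt)] + 1e-9) {
    stop("perturbation_end_time outside the trajectory range")
  }
  keep <- tt >= perturbation_end_time - 1e-12
  sub <- trajectory(tt[keep], traj$states[, keep, drop = FALSE],
                    species = traj$species)
  ct <- convergence_time(sub, spec)
  if (is.na(ct)) NA_real_ else ct - perturbation_end_time
}

#' Critical perturbation strength by bisection (resistance)
#'
#' Resistance is the strongest perturbation a community withstands while
#' still recovering to its initial stable state instead of shifting to an
#' alternative one.  Given a deterministic `outcome` function mapping a
#' perturbation strength to `TRUE` (recovers) or `FALSE` (shifts), the
#' critical strength separating the two regimes is bracketed by bisection.
#' The outcomes at the two initial ends must differ; if they agree the
#' scenario holds no threshold in range (e.g. a monostable community) and a
#' flagged result is returned instead of an error.
#'
#' @param outcome function `strength -> logical` (`TRUE` = recovers).
#' @param lower,upper initial bracket ends.
#' @param tolerance requested bracket width.
#' @return An object of class `fracomm_resistance`: list with `critical`
#'   (the strength at the recovering end of the final bracket), `bracket`,
#'   `outcomes` (logical at both bracket ends), `evaluations` and `flag`
#'   (`"ok"` or `"no-threshold-in-range"`).
#' @export
resistance_threshold <- function(outcome, lower, upper, tolerance) {
  stopifnot(is.function(outcome), lower < upper, tolerance > 0)
  n_eval <- 0L
  eval1 <- function(s) {
    n_eval <<- n_eval + 1L
    isTRUE(outcome(s))
  }
  o_lo <- eval1(lower)
  o_hi <- eval1(upper)
  if (o_lo == o_hi) {
    return(structure(list(critical = NA_real_, bracket = c(lower, upper),
                          outcomes = c(o_lo, o_hi), evaluations = n_eval,
                          flag = "no-threshold-in-range"),
                     class = "fracomm_resistance"))
  }
  lo <- lower
  hi <- upper
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (eval1(mid) == o_lo) lo <- mid else hi <- mid
  }
  critical <- if (o_lo) lo else hi
  structure(list(critical = critical, bracket = c(lo, hi),
                 outcomes = c(o_lo, o_hi), evaluations = n_eval,
                 flag = "ok"),
            class = "fracomm_resistance")
}

#' @export
print.fracomm_resistance <- function(x, ...) {
  if (x$flag == "ok") {
    cat(sprintf("Resistance threshold: %.6g (bracket [%.6g, %.6g], %d evaluations)\n",
                x$critical, x$bracket[1], x$bracket[2], x$evaluations))
  } else {
    cat("Resistance: no threshold in range (same outcome at both ends)\n")
  }
  invisible(x)
}
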