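#' Time-dependent parameter schedules (perturbations)
#'
#' A `fracomm_timeline` holds the base parameter values of a model (named
#' list of numeric vectors, e.g. `list(b = c(1, 1, 1))`) together with an
#' ordered set of pulse segments and optional per-species stochastic paths.
#' Evaluating the timeline at a time `t` returns the base values with every
#' active override applied.  Pulse segments use the half-open convention
#' `[start, end)`: the replacement value applies at `start` and stops
#' applying at `end`.
#'
#' @param base named list of numeric parameter vectors (base values).
#' @param segments `NULL` or a data.frame with columns `species`,
#'   `parameter`, `start`, `end`, `value`; segments for the same
#'   (species, parameter) pair must not overlap.
#' @param paths `NULL` or a list of stochastic paths, each a list with
#'   fields `species`, `parameter`, `times` (strictly increasing) and
#'   `values` (same length); between nodes the preceding node's value
#'   applies.
#' @return An object of class `fracomm_timeline`.
#' @seealso [pulse_timeline()], [alternating_timeline()], [attach_ou_path()]
#' @export
parameter_timeline <- function(base, segments = NULL, paths = NULL) {
  if (!is.list(base) || is.null(names(base)) || any(names(base) == "")) {
    stop("base must be a named list of numeric parameter vectors")
  }
  base <- lapply(base, as.numeric)
  if (!is.null(segments)) {
    segments <- as.data.frame(segments)
    needed <- c("species", "parameter", "start", "end", "value")
    if (!all(needed %in% names(segments))) {
      stop("segments need columns: ", paste(needed, collapse = ", "))
    }
    if (any(segments$start >= segments$end)) {
      stop("invalid-schedule: each segment needs start < end")
    }
    for (key in unique(paste(segments$species, segments$parameter))) {
      sel <- segments[paste(segments$species, segments$parameter) == key, ]
      sel <- sel[order(sel$start), ]
      if (nrow(sel) > 1L && any(sel$start[-1L] < sel$end[-nrow(sel)])) {
        stop("invalid-schedule: overlapping segments for ", key)
      }
    }
    for (p in unique(segments$parameter)) {
      if (is.null(base[[p]])) stop("segment refers to unknown parameter ", p)
      bad <- segments$species[segments$parameter == p]
      if (any(bad < 1L | bad > length(base[[p]]))) {
        stop("segment species index out of range for parameter ", p)
      }
    }
  }
  if (!is.null(paths)) {
    for (pp in paths) {
      if (!all(c("species", "parameter", "times", "values") %in% names(pp))) {
        stop("each path needs species, parameter, times, values")
      }
      if (length(pp$times) != length(pp$values) ||
          any(diff(pp$times) <= 0)) {
        stop("path times must be strictly increasing and match values")
      }
      if (is.null(base[[pp$parameter]])) {
        stop("path refers to unknown parameter ", pp$parameter)
      }
    }
  }
  structure(list(base = base, segments = segments, paths = paths),
            class = "fracomm_timeline")
}

#' Pulse perturbation schedule
#'
#' Builds a timeline in which selected growth (or death) rates are replaced
#' by a fixed value during one or more time windows.  The perturbation
#' strength is the replacement value itself: the value at which the rate is
#' set during the pulse.
#'
#' @param base_params named list of base parameter vectors,
#'   e.g. `list(b = c(1, 1))`.
#' @param pulses data.frame (or list coercible to one) with columns
#'   `species`, `parameter`, `start`, `end`, `value`.  `parameter` defaults
#'   to `"b"` if absent.
#' @return A `fracomm_timeline`.
#' @examples
#' tl <- pulse_timeline(list(b = c(1, 1)),
#'                      data.frame(species = 1, start = 10, end = 20,
#'                                 value = 0.2))
#' evaluate_timeline(tl, 15)$b  # c(0.2, 1)
#' evaluate_timeline(tl, 20)$b  # c(1, 1): half-open [start, end)
#' @export
pulse_timeline <- function(base_params, pulses) {
  pulses <- as.data.frame(pulses)
  if (is.null(pulses$parameter)) pulses$parameter <- "b"
  parameter_timeline(base_params, segments = pulses)
}

#' Alternating (periodic) perturbation schedule
#'
#' Builds `2 * n_cycles` contiguous half-open segments on one species'
#' parameter, alternating between a low and a high value, starting at
#' `start_time`; total covered duration is
#' `2 * n_cycles * segment_duration`.
#'
#' @param base_params named list of base parameter vectors.
#' @param species species index to perturb.
#' @param low_value,high_value values of the alternating segments (low
#'   first).
#' @param segment_duration duration of each half-cycle (> 0).
#' @param n_cycles number of low/high cycles (>= 1).
#' @param start_time time at which the first (low) segment starts.
#' @param parameter perturbed parameter name (default `"b"`).
#' @return A `fracomm_timeline`.
#' @export
alternating_timeline <- function(base_params, species, low_value, high_value,
                                 segment_duration, n_cycles,
                                 start_time = 0, parameter = "b") {
  n_cycles <- as.integer(n_cycles)
  if (is.na(n_cycles) || n_cycles < 1L) stop("n_cycles must be >= 1")
  if (!is.finite(segment_duration) || segment_duration <= 0) {
    stop("segment_duration must be > 0")
  }
  k <- seq_len(2L * n_cycles) - 1L
  segs <- data.frame(
    species = species, parameter = parameter,
    start = start_time + k * segment_duration,
    end = start_time + (k + 1L) * segment_duration,
    value = rep(c(low_value, high_value), n_cycles)
  )
  parameter_timeline(base_params, segments = segs)
}

#' Ornstein-Uhlenbeck process parameters
#'
#' Mean-reverting Gaussian process used to perturb growth rates:
#' \eqn{dx = \theta (m - x) dt + \sigma dW}.
#'
#' @param theta reversion rate (1/time), > 0.
#' @param sigma volatility (parameter units / sqrt(time)), >= 0.
#' @param mean long-run mean `m` (parameter units).
#' @param initial initial value (defaults to `mean`).
#' @return An object of class `fracomm_ou_params`.
#' @export
ou_params <- function(theta, sigma, mean, initial = mean) {
  if (!is.finite(theta) || theta <= 0) {
    stop("invalid-parameter: theta must be > 0")
  }
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(theta = theta, sigma = sigma, mean = mean,
                 initial = initial),
            class = "fracomm_ou_params")
}

#' Sample an Ornstein-Uhlenbeck path on a time grid
#'
#' Uses the exact Gaussian transition density (no discretization error):
#' given a step `dt`, the next value is normal with mean
#' `m + (x - m) exp(-theta dt)` and variance
#' `sigma^2 (1 - exp(-2 theta dt)) / (2 theta)`.  The caller's RNG state is
#' restored afterwards, so the same `seed` always yields the same path.
#'
#' @param params an [ou_params()] object.
#' @param time_grid strictly increasing numeric vector.
#' @param seed integer seed (or `NULL` to use and advance the current RNG).
#' @return numeric vector of the sampled path, same length as `time_grid`.
#' @export
simulate_ou <- function(params, time_grid, seed = NULL) {
  stopifnot(inherits(params, "fracomm_ou_params"))
  time_grid <- as.numeric(time_grid)
  if (length(time_grid) < 1L || any(diff(time_grid) <= 0)) {
    stop("time_grid must be strictly increasing")
  }
  n <- length(time_grid)
  th <- params$theta
  m <- params$mean
  s <- params$sigma
  with_seed(seed, {
    x <- numeric(n)
    x[1L] <- params$initial
    if (n > 1L) {
      dt <- diff(time_grid)
      decay <- exp(-th * dt)
      sd_step <- s * sqrt((1 - exp(-2 * th * dt)) / (2 * th))
      z <- rnorm(n - 1L)
      for (i in seq_len(n - 1L)) {
        x[i + 1L] <- m + (x[i] - m) * decay[i] + sd_step[i] * z[i]
      }
    }
    x
  })
}

#' Attach a stochastic path to a timeline
#'
#' Samples an OU path on the given grid and attaches it to the timeline as
#' the value of `parameter` for `species`.  Growth rates are non-negative,
#' so by default the path is floored at 0; the number of floored nodes is
#' recorded in the returned timeline's `floored` field and reported via a
#' message when positive.
#'
#' @param timeline a `fracomm_timeline` (or base parameter list).
#' @param species species index.
#' @param ou an [ou_params()] object.
#' @param time_grid grid on which to sample the path (should cover the
#'   simulation horizon; the solver holds the preceding node's value between
#'   nodes).
#' @param seed seed for the path.
#' @param parameter parameter name (default `"b"`).
#' @param floor_at_zero clamp negative path values to 0 (default `TRUE`).
#' @return The timeline with the path attached.
#' @export
attach_ou_path <- function(timeline, species, ou, time_grid, seed = NULL,
                           parameter = "b", floor_at_zero = TRUE) {
  if (!inherits(timeline, "fracomm_timeline")) {
    timeline <- parameter_timeline(timeline)
  }
  vals <- simulate_ou(ou, time_grid, seed)
  n_floored <- 0L
  if (floor_at_zero) {
    n_floored <- sum(vals < 0)
    vals[vals < 0] <- 0
  }
  if (n_floored > 0L) {
    message("attach_ou_path: floored ", n_floored,
            " negative growth-rate nodes at 0")
  }
  path <- list(species = as.integer(species), parameter = parameter,
               times = as.numeric(time_grid), values = vals)
  tl <- parameter_timeline(timeline$base, timeline$segments,
                           c(timeline$paths, list(path)))
  tl$floored <- c(timeline$floored, n_floored)
  tl
}

#' Evaluate a timeline at one time point
#'
#' Deterministic lookup combining base values, pulse segments (half-open
#' `[start, end)`) and stochastic paths (piecewise constant: the preceding
#' node's value applies between nodes).  Querying before a stored path's
#' first node is an error.
#'
#' @param timeline a `fracomm_timeline`.
#' @param time query time.
#' @return named list of parameter vectors with overrides applied.
#' @export
evaluate_timeline <- function(timeline, time) {
  stopifnot(inherits(timeline, "fracomm_timeline"))
  out <- timeline$base
  if (!is.null(timeline$segments)) {
    seg <- timeline$segments
    hit <- seg$start <= time & time < seg$end
    if (any(hit)) {
      for (r in which(hit)) {
        out[[seg$parameter[r]]][seg$species[r]] <- seg$value[r]
      }
    }
  }
  if (!is.null(timeline$paths)) {
    for (pp in timeline$paths) {
      i <- findInterval(time, pp$times)
      if (i < 1L) {
        stop("out-of-range: time ", time,
             " precedes the stored stochastic path")
      }
      out[[pp$parameter]][pp$species] <- pp$values[i]
    }
  }
  out
}
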