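#' Define a system of Caputo fractional differential equations
#'
#' Bundles a right-hand side \eqn{F(t, X)}, one derivative order per species,
#' and the initial condition into a system description that [caputo_solve()]
#' can integrate.  Each species \eqn{i} obeys
#' \deqn{D^{\mu_i} X_i = F_i(t, X), \qquad 0 < \mu_i \le 1,}
#' where \eqn{D^{\mu_i}} is the Caputo derivative of order \eqn{\mu_i}.
#' Orders below one introduce a power-law memory kernel: the current rate of
#' change depends on the whole past trajectory, with the influence of past
#' states decaying as a power law.  The *memory strength* of species \eqn{i}
#' is defined as \eqn{1 - \mu_i}; \eqn{\mu_i = 1} recovers the classical
#' memoryless ordinary differential equation.
#'
#' @param rhs function of `(time, state)` returning the derivative vector
#'   \eqn{F(t, X)}, same length as `state`.
#' @param orders numeric vector of derivative orders \eqn{\mu_i}, one per
#'   species, each in (0, 1].  A single value is recycled to all species
#'   (commensurate memory).
#' @param initial_state non-negative numeric vector of initial abundances.
#' @param initial_time starting time \eqn{t_0} (default 0).
#' @param species optional character vector of species names.
#' @return An object of class `fracomm_system`.
#' @seealso [caputo_solve()], [memory_strength()]
#' @examples
#' sys <- fractional_system(function(t, x) -x, orders = 0.5, initial_state = 1)
#' memory_strength(sys)
#' @export
fractional_system <- function(rhs, orders, initial_state, initial_time = 0,
                              species = NULL) {
  stopifnot(is.function(rhs))
  initial_state <- as.numeric(initial_state)
  n <- length(initial_state)
  if (n < 1L) stop("initial_state must contain at least one species")
  if (length(orders) == 1L) orders <- rep(as.numeric(orders), n)
  orders <- as.numeric(orders)
  if (length(orders) != n) {
    stop("orders and initial_state must have identical length")
  }
  if (any(!is.finite(orders)) || any(orders <= 0) || any(orders > 1)) {
    stop("every derivative order must satisfy 0 < mu <= 1")
  }
  if (any(!is.finite(initial_state)) || any(initial_state < 0)) {
    stop("initial_state must be finite and non-negative")
  }
  if (!is.finite(initial_time)) stop("initial_time must be finite")
  f0 <- rhs(initial_time, initial_state)
  if (length(f0) != n || any(!is.finite(f0))) {
    stop("rhs output must be finite and of the same length as initial_state")
  }
  if (is.null(species)) species <- paste0("X_", seq_len(n))
  structure(
    list(rhs = rhs, orders = orders, initial_state = initial_state,
         initial_time = initial_time, species = as.character(species)),
    class = "fracomm_system"
  )
}

#' Memory strength of a fractional system
#'
#' Memory strength is defined as \eqn{1 - \mu_i} per species: 0 is the
#' memoryless (classical) limit, values approaching 1 mean slower kernel
#' decay and stronger influence of the past.
#'
#' @param x a `fracomm_system`, or a numeric vector of orders.
#' @return numeric vector of per-species memory strengths.
#' @export
memory_strength <- function(x) {
  orders <- if (inherits(x, "fracomm_system")) x$orders else as.numeric(x)
  1 - orders
}

#' @export
print.fracomm_system <- function(x, ...) {
  cat("Caputo fractional system:", length(x$initial_state), "species\n")
  cat("  orders mu:", format(x$orders, digits = 4), "\n")
  cat("  memory 1-mu:", format(1 - x$orders, digits = 4), "\n")
  cat("  t0 =", x$initial_time, " X0 =", format(x$initial_state, digits = 4), "\n")
  invisible(x)
}

#' Solver settings for the fractional predictor-corrector scheme
#'
#' @param step_size uniform time step \eqn{h > 0}.
#' @param horizon final time; must exceed the system's initial time.  If
#'   `horizon - initial_time` is not an integer multiple of `step_size`, the
#'   grid is extended by one step past the horizon and the trajectory is cut
#'   at the horizon, the final state being linearly interpolated between the
#'   two bracketing nodes.
#' @param corrector_iterations number of corrector passes per step
#'   (the \eqn{m} of the P(EC)\eqn{^m} scheme), at least 1.
#' @param history_window optional positive integer: number of most recent
#'   steps retained in the memory convolution (short-memory approximation).
#'   `NULL` (default) keeps the full history, which is exact but quadratic
#'   in the number of steps.
#' @param negative_floor non-negative tolerance: abundances in
#'   `[-negative_floor, 0)` are clamped to 0; values below `-negative_floor`
#'   abort the run as a solver misconfiguration.
#' @return An object of class `fracomm_settings`.
#' @export
solver_settings <- function(step_size, horizon, corrector_iterations = 1L,
                            history_window = NULL, negative_floor = 1e-12) {
  if (!is.finite(step_size) || step_size <= 0) stop("step_size must be > 0")
  if (!is.finite(horizon)) stop("horizon must be finite")
  corrector_iterations <- as.integer(corrector_iterations)
  if (is.na(corrector_iterations) || corrector_iterations < 1L) {
    stop("corrector_iterations must be a positive integer")
  }
  if (!is.null(history_window)) {
    history_window <- as.integer(history_window)
    if (is.na(history_window) || history_window < 1L) {
      stop("history_window must be a positive integer or NULL")
    }
  }
  if (!is.finite(negative_floor) || negative_floor < 0) {
    stop("negative_floor must be non-negative")
  }
  structure(
    list(step_size = step_size, horizon = horizon,
         corrector_iterations = corrector_iterations,
         history_window = history_window, negative_floor = negative_floor),
    class = "fracomm_settings"
  )
}

#' Fractional Adams-Bashforth-Moulton quadrature weights
#'
#' Returns the predictor and corrector weights of the fractional
#' Adams-Bashforth-Moulton scheme for a Caputo derivative of order `order` on
#' a uniform grid.  The predictor (fractional rectangle rule) weights are
#' \deqn{b_{j,n+1} = \frac{h^\mu}{\mu}\left((n+1-j)^\mu - (n-j)^\mu\right),}
#' and the corrector (fractional trapezoid) weights are
#' \eqn{h^\mu/(\mu(\mu+1))} times
#' \deqn{a_{j,n+1} = \begin{cases}
#'   n^{\mu+1} - (n-\mu)(n+1)^\mu & j = 0\\
#'   (n-j+2)^{\mu+1} + (n-j)^{\mu+1} - 2(n-j+1)^{\mu+1} & 1 \le j \le n\\
#'   1 & j = n+1.\end{cases}}
#' These are the quadrature coefficients of the discretized power-law memory
#' kernel: node \eqn{j}'s weight in the step to node \eqn{n+1} measures how
#' much the state at \eqn{t_j} still influences the present.  At
#' \eqn{\mu = 1} the kernel collapses to a Dirac delta and the weights reduce
#' to the classical rectangle and trapezoid rules.
#'
#' In the returned matrices, row `n + 1` holds the weights of the step from
#' node `n` to node `n + 1` (`n = 0, ..., n_steps - 1`); unused entries are
#' `NA`.  The solver itself evaluates these weights incrementally and never
#' materializes the full table.
#'
#' @param order derivative order \eqn{\mu} in (0, 1].
#' @param n_steps number of steps to tabulate (rows), at least 1.
#' @param step_size grid spacing \eqn{h > 0}.
#' @return A `fracomm_weights` object: list with `order`, `step_size`,
#'   `predictor` (`n_steps` x `n_steps` matrix, column `j + 1` = node `j`) and
#'   `corrector` (`n_steps` x `n_steps + 1` matrix, last used column of each
#'   row = the new node).
#' @examples
#' w <- caputo_weights(0.5, n_steps = 4, step_size = 1)
#' w$predictor[1, 1]  # (1/0.5) * (1 - 0) = 2
#' @export
caputo_weights <- function(order, n_steps, step_size) {
  if (!is.finite(order) || order <= 0 || order > 1) {
    stop("order must satisfy 0 < mu <= 1")
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  if (!is.finite(step_size) || step_size <= 0) stop("step_size must be > 0")
  mu <- order
  h <- step_size
  cp <- h^mu / mu
  cc <- h^mu / (mu * (mu + 1))
  pred <- matrix(NA_real_, n_steps, n_steps)
  corr <- matrix(NA_real_, n_steps, n_steps + 1L)
  for (n in 0:(n_steps - 1L)) {
    j <- 0:n
    pred[n + 1L, j + 1L] <- cp * ((n + 1 - j)^mu - (n - j)^mu)
    a <- numeric(n + 2L)
    a[1L] <- n^(mu + 1) - (n - mu) * (n + 1)^mu
    if (n >= 1L) {
      jj <- 1:n
      a[jj + 1L] <- (n - jj + 2)^(mu + 1) + (n - jj)^(mu + 1) -
        2 * (n - jj + 1)^(mu + 1)
    }
    a[n + 2L] <- 1
    corr[n + 1L, seq_len(n + 2L)] <- cc * a
  }
  structure(list(order = mu, step_size = h, predictor = pred, corrector = corr),
            class = "fracomm_weights")
}

#' Solve a Caputo fractional system
#'
#' Integrates a [fractional_system()] with the fractional
#' Adams-Bashforth-Moulton predictor-corrector (P(EC)\eqn{^m}) scheme on a
#' uniform grid.  Species may have distinct orders (incommensurate memory):
#' the memory convolution is evaluated per species with its own weight
#' sequence.  For species with \eqn{\mu_i = 1} and full history the scheme
#' reduces to the classical trapezoidal predictor-corrector and is evaluated
#' with running sums (linear cost).
#'
#' @param system a `fracomm_system`.
#' @param settings a `fracomm_settings`.
#' @return A [trajectory()] on the uniform grid (clamped non-negative).
#' @examples
#' sys <- fractional_system(function(t, x) -x, 0.5, initial_state = 1)
#' tr <- caputo_solve(sys, solver_settings(step_size = 0.01, horizon = 1))
#' tail(t(tr$states), 1)  # close to mittag_leffler(0.5, -1)
#' @export
caputo_solve <- function(system, settings) {
  stopifnot(inherits(system, "fracomm_system"),
            inherits(settings, "fracomm_settings"))
  t0 <- system$initial_time
  h <- settings$step_size
  if (settings$horizon <= t0) stop("horizon must exceed the initial time")
  span <- settings$horizon - t0
  n_steps <- floor(span / h + 1e-9)
  rem <- span - n_steps * h
  overshoot <- rem > 1e-9 * h
  if (overshoot) n_steps <- n_steps + 1L
  if (n_steps < 1L) n_steps <- 1L
  rhs <- system$rhs
  wrapped <- function(t, x) {
    out <- as.numeric(rhs(t, x))
    out
  }
  states <- abm_solve_cpp(wrapped, system$initial_state, system$orders,
                          t0, h, as.integer(n_steps),
                          settings$corrector_iterations,
                          if (is.null(settings$history_window)) 0L
                          else settings$history_window,
                          settings$negative_floor)
  times <- t0 + h * (0:n_steps)
  if (overshoot) {
    # cut the trajectory at the horizon: interpolate the final short segment
    tt <- settings$horizon
    w <- (tt - times[n_steps]) / h
    xh <- (1 - w) * states[, n_steps] + w * states[, n_steps + 1L]
    states[, n_steps + 1L] <- pmax(xh, 0)
    times[n_steps + 1L] <- tt
  }
  trajectory(times, states, species = system$species)
}

#' Trajectory container
#'
#' Stores simulated abundances on a time grid: `times` (strictly increasing)
#' and `states`, a species-by-time matrix with one column per grid time.
#'
#' @param times strictly increasing numeric vector.
#' @param states numeric matrix, species x time, non-negative.
#' @param species optional character names for rows of `states`.
#' @return An object of class `fracomm_trajectory`.
#' @export
trajectory <- function(times, states, species = NULL) {
  times <- as.numeric(times)
  if (is.vector(states)) states <- matrix(states, nrow = 1L)
  states <- as.matrix(states)
  if (ncol(states) != length(times)) {
    stop("states must have one column per time point")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(states)) || any(states < -1e-12)) {
    stop("states must be finite and non-negative")
  }
  states[states < 0] <- 0
  if (is.null(species)) species <- paste0("X_", seq_len(nrow(states)))
  rownames(states) <- species
  structure(list(times = times, states = states, species = species),
            class = "fracomm_trajectory")
}

#' @export
print.fracomm_trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x$states), "species x", length(x$times),
      "time points on [", x$times[1], ",", x$times[length(x$times)], "]\n")
  invisible(x)
}

#' @export
as.data.frame.fracomm_trajectory <- function(x, ...) {
  d <- data.frame(time = x$times, t(x$states))
  names(d) <- c("time", x$species)
  d
}

#' Evaluate a trajectory at arbitrary times
#'
#' States between grid nodes are linearly interpolated; times outside the
#' stored range are an error.
#'
#' @param traj a `fracomm_trajectory`.
#' @param at numeric vector of query times.
#' @return matrix species x `length(at)` (drop to a vector for one time).
#' @export
trajectory_state <- function(traj, at) {
  stopifnot(inherits(traj, "fracomm_trajectory"))
  at <- as.numeric(at)
  tr <- range(traj$times)
  if (any(at < tr[1] - 1e-9) || any(at > tr[2] + 1e-9)) {
    stop("query time outside the trajectory range")
  }
  at <- pmin(pmax(at, tr[1]), tr[2])
  out <- vapply(at, function(tt) {
    i <- findInterval(tt, traj$times, rightmost.closed = TRUE)
    if (i >= length(traj$times)) return(traj$states[, length(traj$times)])
    w <- (tt - traj$times[i]) / (traj$times[i + 1L] - traj$times[i])
    (1 - w) * traj$states[, i] + w * traj$states[, i + 1L]
  }, numeric(nrow(traj$states)))
  out <- matrix(out, nrow = nrow(traj$states))
  rownames(out) <- traj$species
  if (length(at) == 1L) out[, 1L] else out
}
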