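#' Simulate a model under optional memory and perturbations
#'
#' One-call wrapper: builds the [fractional_system()] for `model` with the
#' given per-species orders and timeline, and integrates it.
#'
#' @param model a `fracomm_model`.
#' @param orders per-species Caputo orders (scalar recycled); memory
#'   strength is `1 - orders`.
#' @param initial_state initial abundances.
#' @param settings a [solver_settings()].
#' @param timeline optional `fracomm_timeline`.
#' @param initial_time start time (default 0).
#' @return A `fracomm_trajectory`.
#' @export
simulate_model <- function(model, orders, initial_state, settings,
                           timeline = NULL, initial_time = 0) {
  sys <- model_system(model, orders, initial_state, initial_time, timeline)
  caputo_solve(sys, settings)
}

#' Pulse-perturbation scenario
#'
#' Bundles everything needed to study a pulse perturbation of one species'
#' growth rate: the model, the starting state (normally a stable state),
#' the recovery target and the alternative stable states, the pulse window
#' and the solver settings.  Used by [run_pulse_scenario()],
#' [pulse_outcome_fn()] and [memory_sweep()].
#'
#' @param model a `fracomm_model`.
#' @param initial_state starting state of the community.
#' @param stable_state the stable state the community should recover to.
#' @param alternative_states list of alternative stable states it may shift
#'   to instead (may be empty).
#' @param species index of the perturbed species.
#' @param window numeric `c(start, end)` of the pulse.
#' @param strength default pulse strength: the value at which the growth
#'   rate is set during the pulse.
#' @param settings a [solver_settings()].
#' @param threshold Bray-Curtis threshold of the convergence interval used
#'   to decide outcomes (default 0.05).
#' @param parameter perturbed parameter name (default `"b"`).
#' @return An object of class `fracomm_scenario`.
#' @export
pulse_scenario <- function(model, initial_state, stable_state,
                           alternative_states = list(), species, window,
                           strength, settings, threshold = 0.05,
                           parameter = "b") {
  stopifnot(inherits(model, "fracomm_model"),
            inherits(settings, "fracomm_settings"),
            length(window) == 2L, window[1] < window[2])
  structure(list(model = model, initial_state = as.numeric(initial_state),
                 stable_state = as.numeric(stable_state),
                 alternative_states = lapply(alternative_states, as.numeric),
                 species = as.integer(species), window = as.numeric(window),
                 strength = strength, settings = settings,
                 threshold = threshold, parameter = parameter),
            class = "fracomm_scenario")
}

scenario_timeline <- function(scenario, strength = scenario$strength) {
  base <- switch(scenario$model$type,
    gonze = list(b = scenario$model$params$b, k = scenario$model$params$k),
    glv = list(b = scenario$model$params$b),
    stop("pulse scenarios need a gonze or glv model")
  )
  pulse_timeline(base, data.frame(
    species = scenario$species, parameter = scenario$parameter,
    start = scenario$window[1], end = scenario$window[2], value = strength))
}

#' Run a pulse scenario
#'
#' @param scenario a [pulse_scenario()].
#' @param orders per-species Caputo orders.
#' @param strength pulse strength (defaults to the scenario's).
#' @return A `fracomm_trajectory`.
#' @export
run_pulse_scenario <- function(scenario, orders = 1,
                               strength = scenario$strength) {
  simulate_model(scenario$model, orders, scenario$initial_state,
                 scenario$settings,
                 timeline = scenario_timeline(scenario, strength))
}

#' Which stable state does a perturbed trajectory settle into?
#'
#' After the perturbation ends, the trajectory is tracked until it first
#' enters the Bray-Curtis convergence interval of one of the candidate
#' states; the index of that state is returned (`NA` if none is entered
#' within the horizon).
#'
#' @param traj a `fracomm_trajectory`.
#' @param candidates list of candidate states (first = recovery target).
#' @param after only consider times at or after this value.
#' @param threshold Bray-Curtis threshold of the convergence interval.
#' @return integer index into `candidates`, or `NA_integer_`.
#' @export
settled_state_index <- function(traj, candidates, after, threshold) {
  tt <- traj$times
  keep <- tt >= after - 1e-12
  sub <- traj$states[, keep, drop = FALSE]
  entry <- vapply(candidates, function(st) {
    bc <- colSums(abs(sub - st)) / colSums(sub + st)
    i <- which(bc <= threshold)
    if (length(i)) i[1L] else NA_integer_
  }, integer(1))
  if (all(is.na(entry))) return(NA_integer_)
  which.min(entry)
}

#' Recover-or-shift outcome function for resistance bisection
#'
#' Returns a deterministic function mapping a pulse strength to `TRUE`
#' (the community re-enters the convergence interval of its initial stable
#' state first) or `FALSE` (it enters an alternative state's interval
#' first, or never decides within the horizon).  Feed the result to
#' [resistance_threshold()].  The solver horizon should be generous: memory
#' slows recovery, so a horizon around ten times the memoryless convergence
#' time is a reasonable default.
#'
#' @param scenario a [pulse_scenario()]; its `alternative_states` must be
#'   non-empty.
#' @param orders per-species Caputo orders used for every evaluation.
#' @return function `strength -> logical`.
#' @export
pulse_outcome_fn <- function(scenario, orders = 1) {
  force(orders)
  function(strength) {
    traj <- run_pulse_scenario(scenario, orders, strength)
    idx <- settled_state_index(
      traj, c(list(scenario$stable_state), scenario$alternative_states),
      after = scenario$window[2], threshold = scenario$threshold)
    !is.na(idx) && idx == 1L
  }
}

# ---------------------------------------------------------------------------
# experiment drivers

#' Bifurcation scan over a model parameter
#'
#' Simulates every combination of a parameter value and an initial
#' condition to a fixed horizon and records the composition there (not at
#' convergence: long transients near ghost attractors are part of the
#' signal).  Solver failures are recorded per row, not raised.
#'
#' @param model_builder function `value -> fracomm_model`.
#' @param parameter_values numeric grid of the varied parameter.
#' @param initial_conditions list of initial-state vectors.
#' @param orders per-species Caputo orders.
#' @param horizon simulation horizon (composition is read at this time).
#' @param settings [solver_settings()] template; its horizon is overridden.
#' @param parameter_name recorded in the output (default `"parameter"`).
#' @return data.frame with one row per (value, initial condition):
#'   `scenario`, `parameter`, `value`, `ic`, `memory`, `dominant`,
#'   one `rel_*` column per species/group, and `error`.
#' @export
bifurcation_scan <- function(model_builder, parameter_values,
                             initial_conditions, orders = 1, horizon = 1000,
                             settings, parameter_name = "parameter") {
  stopifnot(length(parameter_values) >= 1L,
            length(initial_conditions) >= 1L)
  rows <- list()
  for (vi in seq_along(parameter_values)) {
    model <- model_builder(parameter_values[vi])
    for (ci in seq_along(initial_conditions)) {
      st <- solver_settings(settings$step_size, horizon,
                            settings$corrector_iterations,
                            settings$history_window,
                            settings$negative_floor)
      res <- tryCatch({
        traj <- simulate_model(model, orders, initial_conditions[[ci]], st)
        xh <- trajectory_state(traj, horizon)
        rel <- relative_abundances(xh, model$groups)
        dom <- dominant_group(xh, model$groups)
        list(rel = rel, dom = dom, err = NA_character_)
      }, error = function(e) list(rel = NULL, dom = NA_character_,
                                  err = conditionMessage(e)))
      labels <- if (!is.null(model$groups)) model$groups$labels
                else paste0("X_", seq_len(model$n_species))
      rel <- if (is.null(res$rel)) {
        setNames(rep(NA_real_, length(labels)), labels)
      } else res$rel
      row <- data.frame(scenario = sprintf("v%03d_ic%02d", vi, ci),
                        parameter = parameter_name,
                        value = parameter_values[vi], ic = ci,
                        memory = paste(format(1 - rep_len(orders,
                                         model$n_species), digits = 4),
                                       collapse = "/"),
                        dominant = res$dom, error = res$err)
      for (nm in names(rel)) row[[paste0("rel_", nm)]] <- rel[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Basin-of-attraction sampling with random initial conditions
#'
#' Draws `n_draws` seeded random initial conditions (independent uniform on
#' (0, 1\] per species by default) and, optionally, multiplicative uniform
#' noise on the interaction matrix, simulates each community, and records
#' the dominant group and group relative abundances of the state it settles
#' into.  A draw counts as converged when the right-hand side at the final
#' state is small (relative infinity norm below `equilibrium_tol`);
#' non-convergent draws are kept and flagged with an absent convergence
#' time.  The whole record list is a pure function of `(model, seed)`.
#'
#' @param model a `fracomm_model` (groups recommended).
#' @param n_draws number of simulations (>= 1).
#' @param orders per-species Caputo orders.
#' @param seed master seed; all draws derive from it.
#' @param settings [solver_settings()] (its horizon is the per-draw
#'   simulation horizon).
#' @param ic_sampler function `n -> numeric(n)` sampling one initial state
#'   (default `runif(n)`).
#' @param param_noise_amplitude relative amplitude of multiplicative uniform
#'   noise applied to off-diagonal interaction entries per draw (gonze
#'   models only; default 0.05).
#' @param conv_threshold Bray-Curtis threshold for the convergence time.
#' @param equilibrium_tol relative derivative norm below which the final
#'   state counts as settled.
#' @return data.frame with one row per draw: `draw`, `memory`, `dominant`,
#'   `rel_*` per group, `convergence_time` (NA when not converged),
#'   `converged`, `error`.
#' @export
basin_sample <- function(model, n_draws, orders = 1, seed = 1, settings,
                         ic_sampler = NULL, param_noise_amplitude = 0.05,
                         conv_threshold = 0.02, equilibrium_tol = 1e-4) {
  stopifnot(inherits(model, "fracomm_model"), n_draws >= 1L)
  N <- model$n_species
  if (is.null(ic_sampler)) ic_sampler <- function(n) runif(n)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      list(ic = ic_sampler(N),
           noise = matrix(runif(N * N, -1, 1), N, N))
    })
  })
  labels <- if (!is.null(model$groups)) model$groups$labels
            else paste0("X_", seq_len(N))
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    m_i <- model
    if (param_noise_amplitude > 0 && model$type == "gonze") {
      K <- model$params$K * (1 + param_noise_amplitude * draws[[i]]$noise)
      m_i <- gonze_model(gonze_params(model$params$b, model$params$k, K,
                                      model$params$n),
                         groups = model$groups)
    }
    res <- tryCatch({
      traj <- simulate_model(m_i, orders, draws[[i]]$ic, settings)
      xf <- traj$states[, ncol(traj$states)]
      f <- model_rhs(m_i)(traj$times[length(traj$times)], xf)
      settled <- max(abs(f)) / max(max(xf), 1e-12) < equilibrium_tol
      ct <- if (settled) {
        convergence_time(traj, convergence_spec(xf, conv_threshold))
      } else NA_real_
      list(rel = relative_abundances(xf, model$groups),
           dom = dominant_group(xf, model$groups),
           ct = ct, ok = settled, err = NA_character_)
    }, error = function(e) list(rel = NULL, dom = NA_character_,
                                ct = NA_real_, ok = FALSE,
                                err = conditionMessage(e)))
    rel <- if (is.null(res$rel)) {
      setNames(rep(NA_real_, length(labels)), labels)
    } else res$rel
    row <- data.frame(draw = i,
                      memory = paste(format(1 - rep_len(orders, N),
                                            digits = 4), collapse = "/"),
                      dominant = res$dom, convergence_time = res$ct,
                      converged = res$ok, error = res$err)
    for (nm in names(rel)) row[[paste0("rel_", nm)]] <- rel[[nm]]
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Metric matrix over a grid of two species' memory strengths
#'
#' For a two-species [pulse_scenario()], evaluates a metric at every
#' combination of the two species' memory strengths; the `(0, 0)` cell is
#' the memoryless baseline.  Metrics:
#' * `"recovery_time"` -- time from pulse end to (dwelling) entry of each
#'   convergence interval in `convergence_specs` (one matrix per spec);
#' * `"convergence_time"` -- unperturbed convergence time to the scenario's
#'   stable state at each spec's threshold;
#' * `"resistance"` -- [resistance_threshold()] over `bounds` at each cell.
#' Per-cell failures yield `NA` and a warning rather than aborting the
#' sweep.
#'
#' @param scenario a two-species [pulse_scenario()].
#' @param memory_i,memory_j memory-strength grids (values in \[0, 1)) for
#'   species 1 and 2.
#' @param metric one of `"recovery_time"`, `"convergence_time"`,
#'   `"resistance"`.
#' @param convergence_specs list of [convergence_spec()] objects (for the
#'   two trajectory metrics).
#' @param bounds,tolerance bisection range and bracket width (resistance
#'   only).
#' @return A matrix (or named list of matrices, one per spec) with
#'   `memory_i` on rows and `memory_j` on columns.
#' @export
memory_sweep <- function(scenario, memory_i, memory_j,
                         metric = c("recovery_time", "convergence_time",
                                    "resistance"),
                         convergence_specs = NULL, bounds = NULL,
                         tolerance = 0.01) {
  metric <- match.arg(metric)
  stopifnot(inherits(scenario, "fracomm_scenario"),
            scenario$model$n_species == 2L,
            length(memory_i) >= 1L, length(memory_j) >= 1L)
  if (any(memory_i < 0 | memory_i >= 1) || any(memory_j < 0 | memory_j >= 1)) {
    stop("memory strengths must lie in [0, 1)")
  }
  if (metric %in% c("recovery_time", "convergence_time")) {
    if (is.null(convergence_specs)) {
      stop("convergence_specs required for trajectory metrics")
    }
    if (inherits(convergence_specs, "fracomm_convergence_spec")) {
      convergence_specs <- list(convergence_specs)
    }
  }
  if (metric == "resistance" && is.null(bounds)) {
    stop("bounds required for the resistance metric")
  }
  dims <- list(format(memory_i, digits = 4), format(memory_j, digits = 4))
  empty <- matrix(NA_real_, length(memory_i), length(memory_j),
                  dimnames = dims)
  out <- if (metric == "resistance" || metric == "convergence_time") {
    list(empty)
  } else {
    rep(list(empty), length(convergence_specs))
  }
  for (a in seq_along(memory_i)) {
    for (b in seq_along(memory_j)) {
      orders <- c(1 - memory_i[a], 1 - memory_j[b])
      vals <- tryCatch({
        switch(metric,
          recovery_time = {
            traj <- run_pulse_scenario(scenario, orders)
            vapply(convergence_specs, function(sp) {
              recovery_time(traj, sp, scenario$window[2])
            }, numeric(1))
          },
          convergence_time = {
            traj <- simulate_model(scenario$model, orders,
                                   scenario$initial_state,
                                   scenario$settings)
            vapply(convergence_specs, function(sp) {
              convergence_time(traj, sp)
            }, numeric(1))
          },
          resistance = {
            rt <- resistance_threshold(pulse_outcome_fn(scenario, orders),
                                       bounds[1], bounds[2], tolerance)
            rt$critical
          })
      }, error = function(e) {
        warning("memory_sweep cell (", memory_i[a], ", ", memory_j[b],
                ") failed: ", conditionMessage(e))
        rep(NA_real_, length(out))
      })
      for (s in seq_along(out)) out[[s]][a, b] <- vals[s]
    }
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Critical memory strength separating two basins
#'
#' Bisects the common memory strength of a target species set (all other
#' species memoryless) for the boundary between two dominant-group
#' outcomes from a fixed initial condition: around the threshold, an
#' infinitesimal change in memory flips which group dominates the final
#' state.  Outcomes at both bounds must differ; equal outcomes give a
#' flagged `no-threshold-in-range` result.
#'
#' @param model a `fracomm_model` with groups (or without: species labels).
#' @param target_species integer indices whose memory strength is varied.
#' @param initial_condition starting abundances.
#' @param bounds `c(lower, upper)` memory strengths in \[0, 1), distinct.
#' @param tolerance bracket width at which bisection stops.
#' @param settings [solver_settings()] (horizon = decision horizon).
#' @return list with `critical` (midpoint of the final bracket), `bracket`,
#'   `outcomes` (dominant labels at the original bounds), `evaluations`,
#'   `flag`.
#' @export
memory_threshold_search <- function(model, target_species, initial_condition,
                                    bounds, tolerance, settings) {
  stopifnot(inherits(model, "fracomm_model"), length(bounds) == 2L)
  if (bounds[1] == bounds[2]) {
    stop("invalid-parameter: degenerate memory bounds")
  }
  if (any(bounds < 0 | bounds >= 1)) {
    stop("memory bounds must lie in [0, 1)")
  }
  bounds <- sort(bounds)
  n_eval <- 0L
  outcome <- function(mem) {
    n_eval <<- n_eval + 1L
    orders <- rep(1, model$n_species)
    orders[target_species] <- 1 - mem
    traj <- simulate_model(model, orders, initial_condition, settings)
    dominant_group(traj$states[, ncol(traj$states)], model$groups)
  }
  o_lo <- outcome(bounds[1])
  o_hi <- outcome(bounds[2])
  if (identical(o_lo, o_hi)) {
    return(list(critical = NA_real_, bracket = bounds,
                outcomes = c(o_lo, o_hi), evaluations = n_eval,
                flag = "no-threshold-in-range"))
  }
  lo <- bounds[1]
  hi <- bounds[2]
  while (hi - lo > tolerance) {
    mid <- (lo + hi) / 2
    if (identical(outcome(mid), o_lo)) lo <- mid else hi <- mid
  }
  list(critical = (lo + hi) / 2, bracket = c(lo, hi),
       outcomes = c(o_lo, o_hi), evaluations = n_eval, flag = "ok")
}
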