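#' Write / read a trajectory as CSV
#'
#' Plain-decimal CSV with header `time,X_1,...,X_N`, written at full double
#' precision (17 significant digits) so that a write/read round trip is
#' value-preserving.
#'
#' @param traj a `fracomm_trajectory`.
#' @param path file path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a `fracomm_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fracomm_trajectory"))
  header <- paste(c("time", traj$species), collapse = ",")
  m <- rbind(traj$times, traj$states)
  lines <- apply(m, 2L, function(col) {
    paste(sprintf("%.17g", col), collapse = ",")
  })
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- tryCatch(read.csv(path, check.names = FALSE),
                error = function(e) stop("malformed trajectory CSV: ",
                                         conditionMessage(e)))
  if (nrow(d) == 0L) stop("empty trajectory file: ", path)
  if (names(d)[1L] != "time" || ncol(d) < 2L) {
    stop("trajectory CSV must start with a 'time' column followed by species")
  }
  if (any(diff(d$time) <= 0)) stop("non-monotone times in ", path)
  trajectory(d$time, t(as.matrix(d[, -1L, drop = FALSE])),
             species = names(d)[-1L])
}

# ---------------------------------------------------------------------------
# scenario configs

config_keys <- list(
  top = c("seed", "model", "memory", "solver", "initial_state",
          "perturbation", "metrics", "experiment"),
  model = c("type", "b", "k", "K", "n", "r", "C", "group_builder"),
  group_builder = c("group_sizes", "intra_K", "inter_K", "hill_n", "b", "k",
                    "noise_amplitude", "labels"),
  memory = c("mu", "strength"),
  solver = c("step_size", "horizon", "corrector_iterations",
             "history_window", "negative_floor"),
  perturbation = c("pulses", "alternating", "ou"),
  metrics = c("threshold", "dwell", "reference"),
  experiment = c("driver", "species", "values", "initial_conditions",
                 "horizon", "n_draws", "param_noise_amplitude",
                 "target_species", "bounds", "tolerance", "stable_state",
                 "alternative_states", "window", "strength", "memory_i",
                 "memory_j", "metric", "thresholds")
)

check_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config key", if (length(unknown) > 1L) "s", " at ", path,
         ": ", paste(unknown, collapse = ", "))
  }
}

#' Load and validate a scenario configuration
#'
#' Scenario configs are JSON files with sections `model`, `memory`,
#' `solver`, `initial_state`, and optional `perturbation`, `metrics` and
#' `experiment` sections, plus a `seed`.  Every cross-field constraint of
#' the underlying constructors is checked before any computation; unknown
#' keys are errors, and defaults are filled in and echoed into the run
#' manifest.
#'
#' @param path path to a JSON config file.
#' @return An object of class `fracomm_config`: the validated config with
#'   built `model`, `orders`, `settings`, `timeline` fields, plus the raw
#'   config and its MD5 hash.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("config parse failure: ",
                                           conditionMessage(e)))
  check_keys(raw, config_keys$top, "top level")
  if (is.null(raw$model)) stop("config requires a 'model' section")
  if (is.null(raw$solver)) stop("config requires a 'solver' section")
  check_keys(raw$model, config_keys$model, "model")
  check_keys(raw$solver, config_keys$solver, "solver")
  if (!is.null(raw$memory)) check_keys(raw$memory, config_keys$memory, "memory")
  if (!is.null(raw$perturbation)) {
    check_keys(raw$perturbation, config_keys$perturbation, "perturbation")
  }
  if (!is.null(raw$metrics)) check_keys(raw$metrics, config_keys$metrics, "metrics")
  if (!is.null(raw$experiment)) {
    check_keys(raw$experiment, config_keys$experiment, "experiment")
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  model <- build_config_model(raw$model, seed)

  n_sp <- model$n_species
  orders <- rep(1, n_sp)
  if (!is.null(raw$memory)) {
    if (!is.null(raw$memory$mu) && !is.null(raw$memory$strength)) {
      stop("memory section: give either 'mu' or 'strength', not both")
    }
    if (!is.null(raw$memory$mu)) orders <- rep_len(raw$memory$mu, n_sp)
    if (!is.null(raw$memory$strength)) {
      orders <- 1 - rep_len(raw$memory$strength, n_sp)
    }
  }
  if (any(orders <= 0 | orders > 1)) {
    stop("memory section: every derivative order must satisfy 0 < mu <= 1")
  }

  sv <- raw$solver
  settings <- solver_settings(
    step_size = sv$step_size, horizon = sv$horizon,
    corrector_iterations = if (is.null(sv$corrector_iterations)) 1L
                           else sv$corrector_iterations,
    history_window = sv$history_window,
    negative_floor = if (is.null(sv$negative_floor)) 1e-12
                     else sv$negative_floor)

  initial_state <- raw$initial_state
  if (is.null(initial_state) && is.null(raw$experiment)) {
    stop("config requires 'initial_state' for a simulate-only scenario")
  }
  if (!is.null(initial_state) && length(initial_state) != n_sp) {
    stop("initial_state length does not match the model's species count")
  }

  timeline <- build_config_timeline(raw$perturbation, model, settings, seed)

  metric_spec <- NULL
  if (!is.null(raw$metrics)) {
    if (is.null(raw$metrics$reference) || is.null(raw$metrics$threshold)) {
      stop("metrics section needs 'reference' and 'threshold'")
    }
    metric_spec <- convergence_spec(
      raw$metrics$reference, raw$metrics$threshold,
      if (is.null(raw$metrics$dwell)) 0 else raw$metrics$dwell)
  }

  structure(list(raw = raw, seed = seed, model = model, orders = orders,
                 settings = settings, initial_state = initial_state,
                 timeline = timeline, metric_spec = metric_spec,
                 experiment = raw$experiment,
                 hash = unname(tools::md5sum(path)), path = path),
            class = "fracomm_config")
}

build_config_model <- function(m, seed) {
  if (is.null(m$type)) stop("model section requires 'type'")
  if (!m$type %in% c("gonze", "glv", "logistic")) {
    stop("model type must be gonze, glv or logistic, got: ", m$type)
  }
  if (m$type == "gonze") {
    if (!is.null(m$group_builder)) {
      gb <- m$group_builder
      check_keys(gb, config_keys$group_builder, "model.group_builder")
      do.call(build_group_model, c(gb, list(seed = seed)))
    } else {
      gonze_model(gonze_params(m$b, m$k, as.matrix(m$K), m$n))
    }
  } else if (m$type == "glv") {
    glv_model(glv_params(m$b, as.matrix(m$K)))
  } else {
    logistic_model(logistic_params(m$r, m$C))
  }
}

build_config_timeline <- function(p, model, settings, seed) {
  if (is.null(p)) return(NULL)
  base <- switch(model$type,
    gonze = list(b = model$params$b, k = model$params$k),
    glv = list(b = model$params$b),
    stop("perturbations are not supported for the logistic model"))
  tl <- parameter_timeline(base)
  if (!is.null(p$pulses)) {
    tl <- parameter_timeline(base, segments = as.data.frame(p$pulses))
  }
  if (!is.null(p$alternating)) {
    a <- p$alternating
    alt <- alternating_timeline(base, a$species, a$low_value, a$high_value,
                                a$segment_duration, a$n_cycles,
                                start_time = if (is.null(a$start_time)) 0
                                             else a$start_time)
    tl <- parameter_timeline(base, segments = rbind(tl$segments,
                                                    alt$segments))
  }
  if (!is.null(p$ou)) {
    ou_list <- p$ou
    if (is.data.frame(ou_list)) {
      ou_list <- lapply(seq_len(nrow(ou_list)), function(i) ou_list[i, ])
    }
    grid <- seq(0, settings$horizon, by = settings$step_size)
    for (j in seq_along(ou_list)) {
      o <- ou_list[[j]]
      tl <- attach_ou_path(
        tl, o$species,
        ou_params(o$theta, o$sigma, o$mean,
                  if (is.null(o$initial) || is.na(o$initial)) o$mean
                  else o$initial),
        grid, seed = seed + j)
    }
  }
  tl
}

#' Run a scenario config and write its outputs
#'
#' Executes the scenario described by a validated config -- a plain
#' simulation by default, or the experiment driver named in the
#' `experiment` section (`basin`, `bifurcation`, `threshold`) -- and writes
#' `trajectory.csv` or `records.csv` plus a `manifest.json` (seed, config
#' hash, solver settings, package version) into `out_dir`.  Outputs are a
#' deterministic function of (config, seed).
#'
#' @param config a `fracomm_config` from [load_config()].
#' @param out_dir output directory (created if missing).
#' @return named list of written file paths, invisibly.
#' @export
run_scenario <- function(config, out_dir) {
  stopifnot(inherits(config, "fracomm_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  driver <- if (is.null(config$experiment)) "simulate"
            else config$experiment$driver
  files <- list()
  if (driver == "simulate") {
    traj <- simulate_model(config$model, config$orders,
                           config$initial_state, config$settings,
                           timeline = config$timeline)
    files$trajectory <- file.path(out_dir, "trajectory.csv")
    write_trajectory(traj, files$trajectory)
    if (!is.null(config$metric_spec)) {
      ct <- convergence_time(traj, config$metric_spec)
      files$metrics <- file.path(out_dir, "metrics.csv")
      write.csv(data.frame(metric = "convergence_time",
                           value = ct, flag = is.na(ct)),
                files$metrics, row.names = FALSE)
    }
  } else if (driver == "basin") {
    ex <- config$experiment
    rec <- basin_sample(
      config$model, n_draws = ex$n_draws, orders = config$orders,
      seed = config$seed, settings = config$settings,
      param_noise_amplitude = if (is.null(ex$param_noise_amplitude)) 0.05
                              else ex$param_noise_amplitude)
    files$records <- file.path(out_dir, "records.csv")
    write.csv(rec, files$records, row.names = FALSE)
  } else if (driver == "bifurcation") {
    ex <- config$experiment
    base_model <- config$model
    sp <- ex$species
    builder <- function(v) {
      p <- base_model$params
      p$b[sp] <- v
      if (base_model$type == "gonze") {
        gonze_model(gonze_params(p$b, p$k, p$K, p$n), base_model$groups)
      } else {
        glv_model(glv_params(p$b, p$K), base_model$groups)
      }
    }
    ics <- ex$initial_conditions
    if (is.matrix(ics)) ics <- lapply(seq_len(nrow(ics)), function(i) ics[i, ])
    rec <- bifurcation_scan(builder, ex$values, ics, config$orders,
                            horizon = if (is.null(ex$horizon)) 1000
                                      else ex$horizon,
                            settings = config$settings,
                            parameter_name = paste0("b[", sp, "]"))
    files$records <- file.path(out_dir, "records.csv")
    write.csv(rec, files$records, row.names = FALSE)
  } else if (driver == "threshold") {
    ex <- config$experiment
    res <- memory_threshold_search(config$model, ex$target_species,
                                   config$initial_state, ex$bounds,
                                   ex$tolerance, config$settings)
    files$records <- file.path(out_dir, "records.csv")
    write.csv(data.frame(critical = res$critical,
                         bracket_lo = res$bracket[1],
                         bracket_hi = res$bracket[2],
                         outcome_lo = res$outcomes[1],
                         outcome_hi = res$outcomes[2],
                         evaluations = res$evaluations, flag = res$flag),
              files$records, row.names = FALSE)
  } else {
    stop("unknown experiment driver: ", driver)
  }
  manifest <- list(
    package = "fracomm",
    version = as.character(utils::packageVersion("fracomm")),
    seed = config$seed, config_hash = config$hash,
    config = config$raw,
    outputs = lapply(files, basename))
  files$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(files)
}
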