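# Shared fixtures: models, stable states and solver settings reused across
# test files.  Everything is built in code; the two-species stable states
# are recomputed once per test run from the fixed-point search.

gonze3 <- symmetric_gonze_model(3)
gonze2 <- symmetric_gonze_model(2)

stable_states_of <- function(model, ...) {
  fps <- find_fixed_points(model, ...)
  Filter(function(f) identical(f$stability, "stable"), fps)
}

# two-species bistable states, species-1-dominant first
gonze2_states <- local({
  st <- lapply(stable_states_of(gonze2), `[[`, "state")
  st[order(vapply(st, function(s) -s[1], numeric(1)))]
})

# monostable two-species gLV with +/- interaction (stable coexistence)
glv_coexist <- glv_model(glv_params(c(1, 1), matrix(c(-1, -0.6, 0.4, -1), 2, 2)))

glv_coexist_state <- local({
  st <- stable_states_of(glv_coexist)
  stopifnot(length(st) == 1L)
  st[[1]]$state
})

# standard pulse scenario on the bistable pair: lower the dominant species'
# growth rate during [20, 120]; used by the resistance tests
resistance_scenario <- function(settings = solver_settings(0.1, 800)) {
  pulse_scenario(gonze2, initial_state = gonze2_states[[1]],
                 stable_state = gonze2_states[[1]],
                 alternative_states = gonze2_states[2],
                 species = 1, window = c(20, 120), strength = 0.4,
                 settings = settings)
}

linear_decay_system <- function(mu, x0 = 1) {
  fractional_system(function(t, x) -x, mu, x0)
}
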