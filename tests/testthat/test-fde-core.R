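test_that("fractional systems validate orders, lengths and initial states", {
  f <- function(t, x) -x
  expect_error(fractional_system(f, 1.2, 1), "0 < mu <= 1")
  expect_error(fractional_system(f, 0, 1), "0 < mu <= 1")
  expect_error(fractional_system(f, c(0.5, 0.7), 1), "identical length")
  expect_error(fractional_system(f, 0.5, -1), "non-negative")
  expect_error(
    fractional_system(function(t, x) c(x, x), 0.5, 1), "same length")
  sys <- fractional_system(f, c(0.7, 1), c(2, 3))
  expect_equal(memory_strength(sys), c(0.3, 0))
})

test_that("predictor weights follow the fractional rectangle rule", {
  w <- caputo_weights(0.5, n_steps = 3, step_size = 1)
  expect_equal(w$predictor[1, 1], 2) # (1/0.5) * (1^0.5 - 0^0.5)
  # mu = 1: every predictor weight equals the step size
  w1 <- caputo_weights(1, n_steps = 5, step_size = 0.1)
  expect_equal(w1$predictor[5, 1:5], rep(0.1, 5))
})

test_that("corrector weights at mu = 1 are the trapezoidal rule", {
  w1 <- caputo_weights(1, n_steps = 4, step_size = 0.2)
  expect_equal(w1$corrector[4, 1:5], 0.2 * c(0.5, 1, 1, 1, 0.5))
  expect_equal(w1$corrector[1, 1:2], 0.2 * c(0.5, 0.5))
})

test_that("weights are positive and satisfy the telescoping identity", {
  for (mu in c(0.3, 0.6, 0.9, 1)) {
    for (h in c(0.05, 1)) {
      w <- caputo_weights(mu, n_steps = 7, step_size = h)
      expect_true(all(w$predictor[lower.tri(w$predictor, diag = TRUE)] > 0))
      for (n in 0:6) {
        expect_equal(sum(w$predictor[n + 1, 1:(n + 1)]),
                     (h^mu / mu) * (n + 1)^mu, tolerance = 1e-12)
        expect_true(all(w$corrector[n + 1, 1:(n + 2)] > 0))
      }
    }
  }
  expect_error(caputo_weights(1.5, 3, 0.1), "0 < mu <= 1")
  expect_error(caputo_weights(0.5, 0, 0.1), "n_steps")
  expect_error(caputo_weights(0.5, 3, -1), "step_size")
})

test_that("zero right-hand side keeps the state constant", {
  sys <- fractional_system(function(t, x) c(0, 0), c(0.5, 1), c(2, 3))
  tr <- caputo_solve(sys, solver_settings(0.1, 2))
  expect_true(all(tr$states[1, ] == 2))
  expect_true(all(tr$states[2, ] == 3))
})

test_that("solver matches closed-form solutions of linear problems", {
  # classical exponential decay at mu = 1
  tr <- caputo_solve(linear_decay_system(1), solver_settings(0.005, 5))
  expect_lt(max(abs(tr$states[1, ] - exp(-tr$times))), 1e-4)
  # Mittag-Leffler relaxation at mu = 0.5
  tr <- caputo_solve(linear_decay_system(0.5), solver_settings(0.005, 5))
  expect_lt(max(abs(tr$states[1, ] - mittag_leffler(0.5, -tr$times^0.5))),
            1e-3)
  # constant forcing: D^0.5 X = 1, X0 = 0 has X(t) = t^0.5 / Gamma(1.5)
  sys <- fractional_system(function(t, x) 1, 0.5, 0)
  tr <- caputo_solve(sys, solver_settings(0.005, 5))
  expect_lt(max(abs(tr$states[1, ] - tr$times^0.5 / gamma(1.5))), 1e-6)
})

test_that("incommensurate orders are honored independently per species", {
  # two uncoupled linear decays with different orders solve to their own
  # Mittag-Leffler relaxations
  sys <- fractional_system(function(t, x) -x, c(0.4, 0.9), c(1, 1))
  tr <- caputo_solve(sys, solver_settings(0.005, 3))
  expect_lt(max(abs(tr$states[1, ] - mittag_leffler(0.4, -tr$times^0.4))),
            1e-3)
  expect_lt(max(abs(tr$states[2, ] - mittag_leffler(0.9, -tr$times^0.9))),
            1e-3)
})

test_that("endpoint convergence order is at least 1 and grows with mu", {
  orders <- vapply(c(0.3, 0.5, 0.7, 1), function(mu) {
    errs <- vapply(c(0.02, 0.01, 0.005), function(h) {
      tr <- caputo_solve(linear_decay_system(mu), solver_settings(h, 2))
      ref <- if (mu == 1) exp(-2) else mittag_leffler(mu, -2^mu)
      abs(tr$states[1, ncol(tr$states)] - ref)
    }, numeric(1))
    mean(log2(errs[-3] / errs[-1]))
  }, numeric(1))
  expect_true(all(orders >= 1))
  expect_true(all(diff(orders) > 0)) # increases toward min(2, 1 + mu)
  expect_gt(orders[4], 1.9)          # classical trapezoidal PECE is O(h^2)
})

test_that("memoryless solutions agree with an independent classical solver", {
  skip_if_not_installed("deSolve")
  cases <- list(
    list(model = gonze3, ic = c(0.6, 0.45, 0.3), horizon = 100),
    list(model = glv_coexist, ic = c(0.1, 0.1), horizon = 50),
    list(model = logistic_model(logistic_params(1, 1)), ic = 0.05,
         horizon = 20)
  )
  for (cs in cases) {
    f <- model_rhs(cs$model)
    tr <- simulate_model(cs$model, 1, cs$ic, solver_settings(0.02, cs$horizon))
    ref <- deSolve::ode(y = cs$ic, times = tr$times, parms = NULL,
                        func = function(t, y, p) list(f(t, y)),
                        method = "lsoda", rtol = 1e-11, atol = 1e-12)
    expect_lt(max(abs(t(ref[, -1, drop = FALSE]) - tr$states)), 1e-4)
  }
})

test_that("a covering history window reproduces the full-history solution", {
  sys <- fractional_system(function(t, x) -x, 0.6, 1)
  full <- caputo_solve(sys, solver_settings(0.01, 2))
  covered <- caputo_solve(sys, solver_settings(0.01, 2, history_window = 200))
  expect_lt(max(abs(full$states - covered$states)), 1e-6)
  # a genuinely truncating window is an approximation, not an error
  truncated <- caputo_solve(sys, solver_settings(0.01, 2, history_window = 20))
  expect_true(all(is.finite(truncated$states)))
})

test_that("solver diagnostics name the failing time", {
  blow <- fractional_system(function(t, x) x^2, 1, 2)
  expect_error(caputo_solve(blow, solver_settings(0.01, 10)), "t = ")
  # strong negative excursion beyond the floor aborts
  down <- fractional_system(function(t, x) -50, 1, 0.1)
  expect_error(caputo_solve(down, solver_settings(0.5, 5)),
               "negative_floor")
})

test_that("a non-dividing horizon is cut at the horizon by interpolation", {
  sys <- linear_decay_system(1)
  tr <- caputo_solve(sys, solver_settings(0.4, 1))
  expect_equal(tr$times[length(tr$times)], 1)
  expect_lt(abs(tr$states[1, length(tr$times)] - exp(-1)), 5e-2)
})

test_that("trajectory containers validate and interpolate", {
  expect_error(trajectory(c(0, 1, 1), matrix(0, 1, 3)), "strictly increasing")
  expect_error(trajectory(c(0, 1), matrix(0, 1, 3)), "one column per time")
  tr <- trajectory(c(0, 1, 2), rbind(c(0, 1, 2), c(1, 2, 3)))
  expect_equal(unname(trajectory_state(tr, 0.5)), c(0.5, 1.5))
  expect_equal(unname(trajectory_state(tr, 2)), c(2, 3))
  expect_error(trajectory_state(tr, 2.5), "outside")
  d <- as.data.frame(tr)
  expect_equal(names(d), c("time", "X_1", "X_2"))
})
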