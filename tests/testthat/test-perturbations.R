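test_that("pulse timelines use the half-open segment convention", {
  base <- list(b = c(1, 1))
  tl0 <- pulse_timeline(base, data.frame(species = integer(0),
                                         parameter = character(0),
                                         start = numeric(0), end = numeric(0),
                                         value = numeric(0)))
  expect_equal(evaluate_timeline(tl0, 3)$b, c(1, 1))
  tl <- pulse_timeline(base, data.frame(species = 1, start = 10, end = 20,
                                        value = 0.2))
  expect_equal(evaluate_timeline(tl, 9.99)$b, c(1, 1))
  expect_equal(evaluate_timeline(tl, 10)$b, c(0.2, 1))
  expect_equal(evaluate_timeline(tl, 15)$b, c(0.2, 1))
  expect_equal(evaluate_timeline(tl, 20)$b, c(1, 1))
})

test_that("overlapping segments on one species/parameter are rejected", {
  base <- list(b = c(1, 1))
  expect_error(
    pulse_timeline(base, data.frame(species = 1, start = c(0, 3),
                                    end = c(5, 8), value = c(0.1, 0.2))),
    "invalid-schedule")
  # same windows on different species are fine
  tl <- pulse_timeline(base, data.frame(species = c(1, 2), start = c(0, 3),
                                        end = c(5, 8), value = c(0.1, 0.2)))
  expect_equal(evaluate_timeline(tl, 4)$b, c(0.1, 0.2))
  expect_error(
    pulse_timeline(base, data.frame(species = 1, start = 5, end = 5,
                                    value = 1)), "start < end")
})

test_that("alternating schedules tile the window with low/high segments", {
  base <- list(b = c(1, 1))
  tl <- alternating_timeline(base, species = 1, low_value = 0.2,
                             high_value = 1.8, segment_duration = 5,
                             n_cycles = 1, start_time = 10)
  expect_equal(nrow(tl$segments), 2L)
  expect_equal(evaluate_timeline(tl, 12)$b[1], 0.2)
  expect_equal(evaluate_timeline(tl, 17)$b[1], 1.8)
  # an interior boundary belongs to the following segment
  expect_equal(evaluate_timeline(tl, 15)$b[1], 1.8)
  expect_equal(evaluate_timeline(tl, 20)$b[1], 1)
  tl3 <- alternating_timeline(base, 1, 0.2, 1.8, segment_duration = 2.5,
                              n_cycles = 3)
  expect_equal(nrow(tl3$segments), 6L)
  expect_equal(max(tl3$segments$end) - min(tl3$segments$start),
               2 * 3 * 2.5)
  expect_error(alternating_timeline(base, 1, 0.2, 1.8, 5, 0), "n_cycles")
})

test_that("Ornstein-Uhlenbeck sampling is exact in its deterministic limits", {
  grid <- seq(0, 10, by = 0.1)
  # sigma = 0 starting at the mean: constant
  p <- ou_params(theta = 2, sigma = 0, mean = 1)
  expect_equal(simulate_ou(p, grid, seed = 1), rep(1, length(grid)))
  # sigma = 0 off the mean: exact exponential reversion
  p2 <- ou_params(theta = 0.7, sigma = 0, mean = 1, initial = 3)
  path <- simulate_ou(p2, grid, seed = 1)
  expect_equal(path, 1 + 2 * exp(-0.7 * grid), tolerance = 1e-12)
  expect_error(ou_params(theta = 0, sigma = 1, mean = 0), "theta")
})

test_that("OU paths hit the analytic stationary variance", {
  grid <- seq(0, 1e4, by = 0.1) # 1e5 steps
  p <- ou_params(theta = 1, sigma = 0.5, mean = 0)
  path <- simulate_ou(p, grid, seed = 99)
  tail_part <- path[-(1:1000)]
  v <- var(tail_part)
  target <- 0.5^2 / 2 # sigma^2 / (2 theta)
  # standard error of the variance, corrected for OU autocorrelation
  # (effective sample size n * dt * theta-ish); 3 SE band with slack
  n_eff <- length(tail_part) * 0.1 * 1 / 2
  se <- target * sqrt(2 / n_eff)
  expect_lt(abs(v - target), 3 * se + 0.01 * target)
})

test_that("seeded OU paths are reproducible and leave the caller's RNG alone", {
  grid <- seq(0, 5, by = 0.5)
  p <- ou_params(1, 0.3, 1)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  a <- simulate_ou(p, grid, seed = 7)
  after <- runif(1)
  expect_identical(a, simulate_ou(p, grid, seed = 7))
  expect_identical(before, after)
})

test_that("stochastic paths evaluate piecewise-constant with range checks", {
  base <- list(b = c(1, 1))
  tl <- parameter_timeline(base, paths = list(
    list(species = 2, parameter = "b", times = c(0, 1, 2),
         values = c(0.5, 0.8, 1.1))))
  expect_equal(evaluate_timeline(tl, 0.99)$b, c(1, 0.5))
  expect_equal(evaluate_timeline(tl, 1)$b, c(1, 0.8))
  expect_equal(evaluate_timeline(tl, 5)$b, c(1, 1.1))
  expect_error(evaluate_timeline(tl, -0.5), "out-of-range")
})

test_that("attaching an OU path floors negative growth rates at zero", {
  base <- list(b = c(1, 1))
  grid <- seq(0, 50, by = 0.1)
  p <- ou_params(theta = 1, sigma = 2, mean = 0) # frequently negative
  expect_message(
    tl <- attach_ou_path(base, 1, p, grid, seed = 5), "floored")
  expect_gt(tl$floored, 0)
  vals <- vapply(grid, function(t) evaluate_timeline(tl, t)$b[1], numeric(1))
  expect_true(all(vals >= 0))
})

test_that("an inert timeline changes nothing in the solver output", {
  base <- list(b = gonze3$params$b, k = gonze3$params$k)
  tl <- parameter_timeline(base)
  set <- solver_settings(0.1, 20)
  plain <- simulate_model(gonze3, 0.8, c(0.5, 0.3, 0.2), set)
  with_tl <- simulate_model(gonze3, 0.8, c(0.5, 0.3, 0.2), set,
                            timeline = tl)
  expect_identical(plain$states, with_tl$states)
})
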