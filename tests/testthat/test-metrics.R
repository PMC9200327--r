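test_that("Bray-Curtis dissimilarity matches its definition", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(6, 2), c(2, 2)), 1 / 3)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined-dissimilarity")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("Bray-Curtis is symmetric, bounded, and zero only at identity", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    x <- runif(n, 0, 5)
    y <- runif(n, 0, 5)
    b <- bray_curtis(x, y)
    expect_identical(b, bray_curtis(y, x))
    expect_gte(b, 0)
    expect_lte(b, 1)
    if (b == 0) expect_equal(x, y)
    expect_equal(bray_curtis(x, x), 0)
  }
})

test_that("relative abundances normalize per species and per group", {
  expect_equal(unname(relative_abundances(c(1, 1, 2))), c(0.25, 0.25, 0.5))
  expect_equal(unname(relative_abundances(5)), 1)
  g <- group_structure(list(a = 1:5, b = 6:10, c = 11:15))
  st <- c(rep(0.4, 5), rep(0.2, 5), rep(0.2, 5))
  expect_equal(relative_abundances(st, g),
               c(a = 0.5, b = 0.25, c = 0.25))
  expect_error(relative_abundances(c(0, 0)), "undefined-composition")
})

test_that("dominance picks the largest group and refuses exact ties", {
  g <- group_structure(list(blue = 1:2, red = 3:4))
  expect_identical(dominant_group(c(0.8, 0.1, 0.05, 0.05), g), "blue")
  expect_error(dominant_group(c(0.5, 0, 0.25, 0.25), g),
               "ambiguous-dominance")
  expect_identical(dominant_group(c(0.1, 0.9)), "X_2")
})

test_that("convergence time is the first (dwelling) entry into the interval", {
  tt <- seq(0, 10, by = 0.01)
  # scalar relaxation 1 + off * exp(-t) toward reference 1:
  # BC = d/(2+d), d = off e^{-t}; threshold theta crossed at
  # t* = log(off (1-theta) / (2 theta))
  off <- 0.5
  theta <- 0.05
  tr <- trajectory(tt, matrix(1 + off * exp(-tt), 1))
  sp <- convergence_spec(1, theta)
  tstar <- log(off * (1 - theta) / (2 * theta))
  expect_lt(abs(convergence_time(tr, sp) - tstar), 0.011)
  # already inside: first time point
  expect_equal(convergence_time(tr, convergence_spec(1, 0.9)), 0)
  # never inside within the horizon: absent, distinguishable from a
  # numeric time equal to the horizon
  short <- trajectory(tt[tt <= 1], matrix(1 + off * exp(-tt[tt <= 1]), 1))
  expect_true(is.na(convergence_time(short, sp)))
  expect_false(is.na(convergence_time(tr, convergence_spec(1, 0.5))))
})

test_that("looser thresholds never yield later convergence times", {
  tt <- seq(0, 20, by = 0.05)
  set.seed(7)
  x <- 1 + 0.8 * exp(-0.3 * tt) * (1 + 0.1 * sin(3 * tt))
  tr <- trajectory(tt, matrix(x, 1))
  ths <- c(0.01, 0.02, 0.05, 0.1, 0.2)
  ct <- vapply(ths, function(th) {
    convergence_time(tr, convergence_spec(1, th))
  }, numeric(1))
  expect_true(all(diff(ct) <= 0))
})

test_that("a dwell requirement discards brief transversal crossings", {
  tt <- seq(0, 10, by = 0.01)
  # dips inside the interval on [2, 2.5), leaves, then settles after t = 5
  d <- ifelse(tt >= 5, 0.001, ifelse(tt >= 2 & tt < 2.5, 0.01, 0.5))
  tr <- trajectory(tt, matrix(1 + d, 1))
  sp0 <- convergence_spec(1, 0.01, dwell = 0)
  spd <- convergence_spec(1, 0.01, dwell = 2)
  t0 <- convergence_time(tr, sp0)
  td <- convergence_time(tr, spd)
  expect_lt(t0, 5)
  expect_gt(td, 5 - 1e-9)
})

test_that("recovery time is convergence time measured after the pulse ends", {
  tt <- seq(0, 10, by = 0.01)
  st <- c(0.99, 0.01)
  tr <- trajectory(tt, matrix(rep(st, length(tt)), nrow = 2))
  sp <- convergence_spec(st, 0.02)
  expect_equal(recovery_time(tr, sp, 3), 0)
  # shifted, never recovering
  tr2 <- trajectory(tt, matrix(rep(rev(st), length(tt)), nrow = 2))
  expect_true(is.na(recovery_time(tr2, sp, 3)))
  expect_error(recovery_time(tr, sp, 99), "outside")
  # synthetic relaxation entered only after the perturbation end
  x <- 1 + 0.5 * exp(-(tt - 3)) * (tt >= 3) + 0.5 * (tt < 3)
  tr3 <- trajectory(tt, matrix(x, 1))
  sp3 <- convergence_spec(1, 0.05)
  tstar <- log(0.5 * (1 - 0.05) / (2 * 0.05))
  expect_lt(abs(recovery_time(tr3, sp3, 3) - tstar), 0.011)
})

test_that("resistance bisection matches an exhaustive scan and flags
           monostable scenarios", {
  # synthetic deterministic outcome with a known critical strength
  crit <- 0.6180339
  outcome <- function(s) s > crit
  r <- resistance_threshold(outcome, 0, 1, tolerance = 1e-4)
  expect_identical(r$flag, "ok")
  expect_lte(r$bracket[2] - r$bracket[1], 1e-4)
  expect_true(r$bracket[1] <= crit && crit <= r$bracket[2])
  expect_equal(r$critical, r$bracket[2]) # the recovering end
  # exhaustive scan at resolution = tolerance agrees
  grid <- seq(0, 1, by = 1e-4)
  scan_crit <- grid[which(vapply(grid, outcome, logical(1)))[1]]
  expect_lt(abs(r$critical - scan_crit), 2e-4)
  # same outcome at both ends: flagged, not an error
  r2 <- resistance_threshold(function(s) TRUE, 0, 1, 0.01)
  expect_identical(r2$flag, "no-threshold-in-range")
  expect_true(is.na(r2$critical))
})

test_that("scenario-level resistance agrees with a brute-force strength scan", {
  sc <- resistance_scenario(solver_settings(0.1, 500))
  outcome <- pulse_outcome_fn(sc, orders = 1)
  tol <- 0.05
  r <- resistance_threshold(outcome, 0, 1, tolerance = tol)
  expect_identical(r$flag, "ok")
  grid <- seq(0, 1, by = tol)
  og <- vapply(grid, outcome, logical(1))
  scan_crit <- grid[which(og)[1]]
  expect_lte(abs(r$critical - scan_crit), tol + 1e-9)
  # post hoc: the bracket really contains the outcome sign change
  expect_false(outcome(r$bracket[1]))
  expect_true(outcome(r$bracket[2]))
})
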