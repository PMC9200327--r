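test_that("Hill-inhibition right-hand side matches direct evaluation", {
  p <- gonze3$params
  expect_equal(gonze_rhs(0, c(0, 0, 0), p), c(0, 0, 0))
  # a lone species at its equilibrium b/k = 1 has zero derivative, and the
  # absent species contribute exactly zero
  expect_equal(gonze_rhs(0, c(1, 0, 0), p), c(0, 0, 0))
  # symmetric interior state: each component 0.5 * ((0.01/0.26)^2 - 0.5)
  v <- 0.5 * ((0.01 / 0.26)^2 - 0.5)
  expect_equal(gonze_rhs(0, c(0.5, 0.5, 0.5), p), rep(v, 3),
               tolerance = 1e-12)
  expect_error(gonze_rhs(0, c(-0.1, 0, 0), p), "invalid-state")
})

test_that("gLV right-hand side matches direct evaluation", {
  p <- glv_params(c(1, 1), matrix(c(-1, -0.25, -0.5, -1), 2, 2))
  expect_equal(glv_rhs(0, c(0, 0), p), c(0, 0))
  expect_equal(glv_rhs(0, c(1, 2), p), c(-1, -2.5))
  p1 <- glv_params(1, matrix(-1, 1, 1))
  expect_equal(glv_rhs(0, 1, p1), 0) # carrying-capacity fixed point
  expect_error(glv_rhs(0, c(1, 2, 3), p), "invalid-parameter")
})

test_that("logistic right-hand side and fixed points are the textbook ones", {
  p <- logistic_params(1, 1)
  expect_equal(logistic_rhs(0, p), 0)
  expect_equal(logistic_rhs(1, p), 0)
  expect_equal(logistic_rhs(0.5, p), 0.25)
  fps <- find_fixed_points(logistic_model(p))
  states <- sort(vapply(fps, function(f) f$state, numeric(1)))
  expect_equal(states, c(0, 1), tolerance = 1e-8)
  labels <- vapply(fps, `[[`, "", "stability")
  expect_setequal(labels, c("unstable", "stable"))
})

test_that("group-model builder produces the block structure it promises", {
  m <- build_group_model(c(5, 5, 5), intra_K = 1, inter_K = 0.1,
                         noise_amplitude = 0)
  expect_equal(m$n_species, 15L)
  gid <- rep(1:3, each = 5)
  same <- outer(gid, gid, `==`)
  expect_true(all(m$params$K[same] == 1))
  expect_true(all(m$params$K[!same] == 0.1))
  # determinism: same seed, same parameters
  m1 <- build_group_model(c(3, 3), 1, 0.2, noise_amplitude = 0.05, seed = 4)
  m2 <- build_group_model(c(3, 3), 1, 0.2, noise_amplitude = 0.05, seed = 4)
  expect_identical(m1$params$K, m2$params$K)
  # every noisy entry stays within the relative amplitude of its block value
  base <- build_group_model(c(3, 3), 1, 0.2, noise_amplitude = 0)$params$K
  expect_true(all(abs(m1$params$K / base - 1) <= 0.05 + 1e-12))
  expect_error(build_group_model(c(3, 3), 0.1, 1), "inter_K < intra_K")
  expect_error(build_group_model(c(0, 3), 1, 0.1), "positive integers")
})

test_that("the symmetric 3-species community is tristable", {
  fps <- find_fixed_points(gonze3)
  states <- lapply(fps, `[[`, "state")
  # the exclusion states are present as (unstable) fixed points
  for (i in 1:3) {
    e <- rep(0, 3); e[i] <- 1
    expect_true(any(vapply(states, function(s) sqrt(sum((s - e)^2)) < 1e-6,
                           logical(1))))
  }
  stable <- Filter(function(f) identical(f$stability, "stable"), fps)
  expect_length(stable, 3)
  doms <- sort(vapply(stable, function(f) which.max(f$state), integer(1)))
  expect_equal(doms, 1:3)
  for (f in stable) expect_gt(max(f$state) / sum(f$state), 0.9)
  # the interior symmetric point exists and is unstable; its coordinate
  # solves b (K^n / (K^n + x^n))^2 = k x, checked against a 1-d bracketing
  # oracle
  g <- function(x) (0.01 / (0.01 + x^2))^2 - x
  xsym <- uniroot(g, c(0.05, 0.5), tol = 1e-12)$root
  i <- which(vapply(fps, function(f) {
    sqrt(sum((f$state - rep(xsym, 3))^2)) < 1e-6
  }, logical(1)))
  expect_length(i, 1)
  expect_identical(fps[[i]]$stability, "unstable")
})

test_that("the 2-species variant is bistable with one dominant species each", {
  stable <- stable_states_of(gonze2)
  expect_length(stable, 2)
  doms <- sort(vapply(stable, function(f) which.max(f$state), integer(1)))
  expect_equal(doms, 1:2)
})

test_that("biased initial conditions reach the three distinct stable states", {
  # the suppressed species relax on a slow O(1/f) ~ 100 time-unit scale,
  # so the horizon must be several multiples of that
  set <- solver_settings(0.1, 800)
  finals <- lapply(list(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8)),
                   function(ic) {
    tr <- simulate_model(gonze3, 1, ic, set)
    tr$states[, ncol(tr$states)]
  })
  expect_equal(vapply(finals, which.max, integer(1)), 1:3)
  stable <- stable_states_of(gonze3)
  for (fin in finals) {
    d <- min(vapply(stable, function(f) sqrt(sum((f$state - fin)^2)),
                    numeric(1)))
    expect_lt(d, 1e-3)
  }
})

test_that("stability labels follow the Matignon criterion", {
  # logistic at X = C: eigenvalue -r, stable at mu = 1
  lm <- logistic_model(logistic_params(2, 3))
  expect_identical(classify_stability(lm, 3, order = 1)$stability, "stable")
  # origin of the symmetric community: eigenvalues b_i > 0, unstable; checked
  # against an independent finite-difference Jacobian
  cl <- classify_stability(gonze3, c(0, 0, 0), order = 1)
  expect_identical(cl$stability, "unstable")
  J <- matrix(0, 3, 3)
  f0 <- gonze_rhs(0, c(0, 0, 0), gonze3$params)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- 1e-6
    J[, j] <- (gonze_rhs(0, e, gonze3$params) - f0) / 1e-6
  }
  expect_equal(sort(Re(cl$eigenvalues)), sort(Re(eigen(J)$values)),
               tolerance = 1e-4)
  # synthetic eigenvalue pair at arg +/- 0.4 pi: unstable for mu = 1
  # (0.4 pi < pi/2) but stable for mu = 0.5 (0.4 pi > pi/4)
  ev <- complex(modulus = c(1, 1), argument = c(0.4, -0.4) * pi)
  expect_identical(fracomm:::matignon_label(ev, 1), "unstable")
  expect_identical(fracomm:::matignon_label(ev, 0.5), "stable")
  # boundary and singular cases are undetermined
  expect_identical(fracomm:::matignon_label(complex(real = 0), 1),
                   "undetermined")
  expect_identical(
    fracomm:::matignon_label(complex(modulus = 1, argument = pi / 2), 1),
    "undetermined")
  expect_error(classify_stability(gonze3, c(0, 0, 0), order = 1.5),
               "order")
})

test_that("states stable at mu = 1 attract nearby memoryless trajectories", {
  set <- solver_settings(0.1, 800)
  for (f in stable_states_of(gonze3)) {
    ic <- pmax(f$state + c(0.02, -0.01, 0.015), 0)
    tr <- simulate_model(gonze3, 1, ic, set)
    expect_lt(sqrt(sum((tr$states[, ncol(tr$states)] - f$state)^2)), 1e-3)
  }
})

test_that("rescaling rates rescales time exactly (unit-handling sanity)", {
  c_fac <- 3.7
  x <- c(0.4, 0.2, 0.7)
  p <- gonze3$params
  p_scaled <- gonze_params(p$b * c_fac, p$k * c_fac, p$K, p$n)
  expect_equal(gonze_rhs(0, x, p_scaled), c_fac * gonze_rhs(0, x, p))
  g <- glv_coexist$params
  g_scaled <- glv_params(g$b * c_fac, g$K * c_fac)
  expect_equal(glv_rhs(0, x[1:2], g_scaled), c_fac * glv_rhs(0, x[1:2], g))
})
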