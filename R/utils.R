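# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Finite-difference Jacobian that never evaluates `f` at negative states:
# central differences in the interior, forward differences at the
# non-negativity boundary.
num_jacobian <- function(f, x, eps = 1e-7) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x
    xp[j] <- x[j] + h
    if (x[j] - h >= 0) {
      xm <- x
      xm[j] <- x[j] - h
      J[, j] <- (f(xp) - f(xm)) / (2 * h)
    } else {
      J[, j] <- (f(xp) - f0) / h
    }
  }
  J
}

# Damped Newton iteration projected onto the non-negative orthant.
newton_root <- function(fn, x0, tol = 1e-10, max_iter = 100) {
  x <- pmax(as.numeric(x0), 0)
  fx <- tryCatch(fn(x), error = function(e) NULL)
  if (is.null(fx)) return(list(converged = FALSE))
  for (it in seq_len(max_iter)) {
    r <- sqrt(sum(fx^2))
    if (r < tol) return(list(root = x, residual = r, converged = TRUE))
    J <- num_jacobian(fn, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) {
      step <- tryCatch(solve(J + diag(1e-8, length(x)), -fx),
                       error = function(e) NULL)
    }
    if (is.null(step) || any(!is.finite(step))) {
      return(list(converged = FALSE))
    }
    lam <- 1
    xn <- x
    fn_new <- fx
    repeat {
      cand <- pmax(x + lam * step, 0)
      fc <- tryCatch(fn(cand), error = function(e) NULL)
      if (!is.null(fc) && all(is.finite(fc)) && sqrt(sum(fc^2)) < r) {
        xn <- cand
        fn_new <- fc
        break
      }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    if (identical(xn, x)) return(list(root = x, residual = r, converged = FALSE))
    x <- xn
    fx <- fn_new
  }
  r <- sqrt(sum(fx^2))
  list(root = x, residual = r, converged = r < tol)
}
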