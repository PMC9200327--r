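#' Parameters of the Hill-inhibition (Gonze-type) community model
#'
#' The model couples logistic-like self-limited growth with multiplicative
#' Hill-function inhibition by every other species:
#' \deqn{\frac{dX_i}{dt} = X_i\left(b_i f_i(\{X_k\}) - k_i X_i\right),\qquad
#'  f_i = \prod_{k \ne i} \frac{K_{ik}^n}{K_{ik}^n + X_k^n},}
#' where \eqn{b_i} is the growth rate, \eqn{k_i} the density-dependent death
#' rate, \eqn{K_{ij}} the inhibition constant of species \eqn{j} on species
#' \eqn{i} (the lower, the stronger the inhibition), and \eqn{n} the Hill
#' coefficient.  Sufficiently strong mutual inhibition (small \eqn{K_{ij}})
#' makes the community multistable, each stable state dominated by one
#' species or group of species.
#'
#' @param b growth-rate vector (1/time), all positive.
#' @param k death-rate vector (1/(time x abundance)), all positive.
#' @param K square interaction-constant matrix (abundance units); only
#'   off-diagonal entries enter the dynamics, and all must be positive.
#' @param n Hill coefficient, > 0.
#' @return An object of class `fracomm_gonze_params`.
#' @export
gonze_params <- function(b, k, K, n) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (ncol(K) != N) stop("K must be square")
  if (length(b) == 1L) b <- rep(b, N)
  if (length(k) == 1L) k <- rep(k, N)
  if (length(b) != N || length(k) != N) {
    stop("b and k must match the side length of K")
  }
  if (any(b <= 0) || any(k <= 0)) stop("all b_i and k_i must be positive")
  off <- K[row(K) != col(K)]
  if (any(!is.finite(off)) || any(off <= 0)) {
    stop("all off-diagonal K_ij must be positive and finite")
  }
  if (!is.finite(n) || n <= 0) stop("Hill coefficient n must be > 0")
  structure(list(b = as.numeric(b), k = as.numeric(k), K = K, n = n),
            class = "fracomm_gonze_params")
}

#' Parameters of the pairwise generalized Lotka-Volterra model
#'
#' \deqn{\frac{dX_i}{dt} = X_i\left(b_i + \sum_j K_{ij} X_j\right),}
#' with growth rates \eqn{b_i} and an interaction matrix whose diagonal
#' holds the intra-specific (self-limitation) coefficients.
#'
#' @param b growth-rate vector.
#' @param K square interaction matrix including the diagonal.
#' @return An object of class `fracomm_glv_params`.
#' @export
glv_params <- function(b, K) {
  K <- as.matrix(K)
  N <- nrow(K)
  if (ncol(K) != N) stop("K must be square")
  if (length(b) == 1L) b <- rep(b, N)
  if (length(b) != N) stop("length of b must match the side of K")
  if (any(!is.finite(b)) || any(!is.finite(K))) {
    stop("parameters must be finite")
  }
  structure(list(b = as.numeric(b), K = K), class = "fracomm_glv_params")
}

#' Logistic growth parameters
#'
#' The single-species test model \eqn{dX/dt = r X (1 - X/C)} with growth
#' rate `r` and carrying capacity `C`.
#'
#' @param r growth rate (1/time), > 0.
#' @param C carrying capacity (abundance), > 0.
#' @return An object of class `fracomm_logistic_params`.
#' @export
logistic_params <- function(r, C) {
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  if (!is.finite(C) || C <= 0) stop("C must be > 0")
  structure(list(r = r, C = C), class = "fracomm_logistic_params")
}

#' Group structure of a community
#'
#' @param members named list of integer vectors; the vectors must partition
#'   `1:N` for some `N`, one non-empty vector per group.
#' @return An object of class `fracomm_groups`.
#' @export
group_structure <- function(members) {
  if (is.null(names(members)) || any(names(members) == "")) {
    stop("every group must be named")
  }
  idx <- sort(unlist(members, use.names = FALSE))
  if (any(lengths(members) == 0L)) stop("every group needs >= 1 species")
  if (!identical(idx, seq_along(idx))) {
    stop("groups must partition the species set 1..N")
  }
  structure(list(members = lapply(members, as.integer),
                 labels = names(members)),
            class = "fracomm_groups")
}

# ---------------------------------------------------------------------------
# model container

#' Community model objects
#'
#' `gonze_model()`, `glv_model()` and `logistic_model()` wrap a parameter set
#' (and optionally a [group_structure()]) into a `fracomm_model` that the
#' solver, fixed-point analysis and experiment drivers consume.
#'
#' @param params the matching parameter object.
#' @param groups optional [group_structure()].
#' @return An object of class `fracomm_model`.
#' @export
gonze_model <- function(params, groups = NULL) {
  stopifnot(inherits(params, "fracomm_gonze_params"))
  new_model("gonze", params, length(params$b), groups)
}

#' @rdname gonze_model
#' @export
glv_model <- function(params, groups = NULL) {
  stopifnot(inherits(params, "fracomm_glv_params"))
  new_model("glv", params, length(params$b), groups)
}

#' @rdname gonze_model
#' @export
logistic_model <- function(params) {
  stopifnot(inherits(params, "fracomm_logistic_params"))
  new_model("logistic", params, 1L, NULL)
}

new_model <- function(type, params, n_species, groups) {
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "fracomm_groups"))
    if (length(unlist(groups$members)) != n_species) {
      stop("group structure does not match the number of species")
    }
  }
  structure(list(type = type, params = params, n_species = n_species,
                 groups = groups),
            class = "fracomm_model")
}

#' @export
print.fracomm_model <- function(x, ...) {
  cat("fracomm model <", x$type, ">:", x$n_species, "species")
  if (!is.null(x$groups)) {
    cat(";", length(x$groups$members), "groups (",
        paste(x$groups$labels, collapse = ", "), ")")
  }
  cat("\n")
  invisible(x)
}

#' Symmetric mutual-inhibition community with default multistable parameters
#'
#' Builds the symmetric Hill-inhibition model with `b = k = 1`,
#' `K_ij = 0.1`, `n = 2` for `n_species` species.  With these constants the
#' 3-species community is tristable (three stable states, each dominated by
#' one species) and the 2-species community is bistable; the package's tests
#' verify this via [find_fixed_points()] rather than assuming it.
#'
#' @param n_species number of species (>= 2).
#' @param K inhibition constant for every pair (default 0.1).
#' @param b,k growth and death rates (defaults 1).
#' @param hill_n Hill coefficient (default 2).
#' @return A `fracomm_model`.
#' @export
symmetric_gonze_model <- function(n_species = 3, K = 0.1, b = 1, k = 1,
                                  hill_n = 2) {
  Km <- matrix(K, n_species, n_species)
  gonze_model(gonze_params(b = b, k = k, K = Km, n = hill_n))
}

#' Block-structured multi-group community builder
#'
#' Builds a Hill-inhibition community whose interaction constants depend only
#' on group membership: within-group pairs get `intra_K`, between-group pairs
#' `inter_K`, each optionally perturbed by seeded multiplicative uniform
#' noise.  Between-group inhibition stronger than within-group inhibition
#' (`inter_K < intra_K`, smaller constant = stronger inhibition) produces a
#' community that is multistable at the group level, each stable state
#' dominated by one group.
#'
#' @param group_sizes integer vector of group sizes (e.g. `c(5, 5, 5)`).
#' @param intra_K within-group inhibition constant.
#' @param inter_K between-group inhibition constant; must be `< intra_K`.
#' @param hill_n Hill coefficient.
#' @param b,k growth / death rates (scalar or per species).
#' @param noise_amplitude relative amplitude of multiplicative uniform noise
#'   on each off-diagonal K entry (0 = exact block structure).
#' @param seed optional seed making the noise reproducible.
#' @param labels group labels; defaults to `"blue"`, `"red"`, `"green"`, ...
#' @return A `fracomm_model` carrying both the parameters and the
#'   [group_structure()].
#' @export
build_group_model <- function(group_sizes, intra_K, inter_K, hill_n = 2,
                              b = 1, k = 1, noise_amplitude = 0, seed = NULL,
                              labels = NULL) {
  group_sizes <- as.integer(group_sizes)
  if (any(is.na(group_sizes)) || any(group_sizes < 1L)) {
    stop("group sizes must be positive integers")
  }
  if (!is.finite(intra_K) || !is.finite(inter_K) ||
      intra_K <= 0 || inter_K <= 0) {
    stop("interaction constants must be positive")
  }
  if (inter_K >= intra_K) {
    stop("between-group inhibition must be stronger: inter_K < intra_K")
  }
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  if (is.null(labels)) {
    labels <- c("blue", "red", "green",
                paste0("group", seq_len(max(0, length(group_sizes) - 3))))
    labels <- labels[seq_along(group_sizes)]
  }
  N <- sum(group_sizes)
  gid <- rep(seq_along(group_sizes), group_sizes)
  K <- matrix(inter_K, N, N)
  same <- outer(gid, gid, `==`)
  K[same] <- intra_K
  if (noise_amplitude > 0) {
    noise <- with_seed(seed, matrix(runif(N * N, -1, 1), N, N))
    K <- K * (1 + noise_amplitude * noise)
  }
  diag(K) <- intra_K # unused by the k != i product; kept positive
  members <- split(seq_len(N), gid)
  names(members) <- labels
  gonze_model(gonze_params(b = b, k = k, K = K, n = hill_n),
              groups = group_structure(members))
}

# ---------------------------------------------------------------------------
# right-hand sides

#' Right-hand side of the Hill-inhibition community model
#'
#' @param time current time (used only to evaluate `timeline`).
#' @param state non-negative abundance vector.
#' @param params a [gonze_params()] object.
#' @param timeline optional [pulse_timeline()]-style schedule overriding
#'   growth/death rates at `time`.
#' @param validate check non-negativity of `state` (disable only for
#'   internal root finding).
#' @return derivative vector \eqn{X_i (b_i f_i - k_i X_i)}.
#' @export
gonze_rhs <- function(time, state, params, timeline = NULL, validate = TRUE) {
  x <- as.numeric(state)
  if (validate && any(x < 0)) stop("invalid-state: negative abundance")
  b <- params$b
  k <- params$k
  if (!is.null(timeline)) {
    v <- evaluate_timeline(timeline, time)
    if (!is.null(v$b)) b <- v$b
    if (!is.null(v$k)) k <- v$k
  }
  N <- length(x)
  Kn <- params$K^params$n
  xn <- abs(x)^params$n
  Tm <- Kn / (Kn + matrix(xn, N, N, byrow = TRUE))
  diag(Tm) <- 1
  f <- exp(rowSums(log(Tm)))
  x * (b * f - k * x)
}

#' Right-hand side of the generalized Lotka-Volterra model
#'
#' @inheritParams gonze_rhs
#' @param params a [glv_params()] object.
#' @return derivative vector \eqn{X_i (b_i + \sum_j K_{ij} X_j)}.
#' @export
glv_rhs <- function(time, state, params, timeline = NULL, validate = TRUE) {
  x <- as.numeric(state)
  if (length(x) != length(params$b)) {
    stop("invalid-parameter: state and parameter dimensions differ")
  }
  if (validate && any(x < 0)) stop("invalid-state: negative abundance")
  b <- params$b
  if (!is.null(timeline)) {
    v <- evaluate_timeline(timeline, time)
    if (!is.null(v$b)) b <- v$b
  }
  x * (b + drop(params$K %*% x))
}

#' Right-hand side of the logistic model
#'
#' @param state abundance (scalar).
#' @param params a [logistic_params()] object.
#' @return \eqn{r X (1 - X/C)}.
#' @export
logistic_rhs <- function(state, params) {
  params$r * state * (1 - state / params$C)
}

#' Right-hand-side closure for a model
#'
#' @param model a `fracomm_model`.
#' @param timeline optional parameter timeline (perturbation schedule).
#' @param validate forwarded to the model's rhs.
#' @return function `(time, state) -> derivative vector`.
#' @export
model_rhs <- function(model, timeline = NULL, validate = TRUE) {
  stopifnot(inherits(model, "fracomm_model"))
  p <- model$params
  switch(model$type,
    gonze = function(t, x) gonze_rhs(t, x, p, timeline, validate),
    glv = function(t, x) glv_rhs(t, x, p, timeline, validate),
    logistic = function(t, x) logistic_rhs(x, p),
    stop("unknown model type")
  )
}

#' Build a fractional system from a model
#'
#' Convenience wrapper combining a model, per-species derivative orders and
#' an initial condition into a [fractional_system()].
#'
#' @param model a `fracomm_model`.
#' @param orders per-species Caputo orders (scalar recycled).
#' @param initial_state initial abundances.
#' @param initial_time start time.
#' @param timeline optional perturbation schedule.
#' @return A `fracomm_system`.
#' @export
model_system <- function(model, orders, initial_state, initial_time = 0,
                         timeline = NULL) {
  species <- if (!is.null(model$groups)) {
    g <- rep(NA_character_, model$n_species)
    for (lab in model$groups$labels) g[model$groups$members[[lab]]] <- lab
    paste0(g, "_", seq_len(model$n_species))
  } else {
    paste0("X_", seq_len(model$n_species))
  }
  fractional_system(model_rhs(model, timeline), orders, initial_state,
                    initial_time, species = species)
}

# ---------------------------------------------------------------------------
# fixed points and stability

#' Locate fixed points of a community model
#'
#' Multi-start damped Newton root search (projected onto non-negative
#' abundances) from a structured set of guesses: the origin, all
#' single-species states, dominance patterns (one species high, the others
#' low), uniform states, and -- for up to three species -- a coarse lattice.
#' For gLV models the exact subset solutions of the linear interior systems
#' are used as additional starts.  Roots are deduplicated by Euclidean
#' distance and classified with [classify_stability()].
#'
#' @param model a `fracomm_model`.
#' @param guesses optional list/matrix of additional starting points (rows).
#' @param tolerance residual norm below which a root is accepted.
#' @param order common derivative order used for the stability
#'   classification (default 1 = memoryless).
#' @param lattice_points lattice resolution per dimension for N <= 3.
#' @return list of `fracomm_fixed_point` objects (fields `state`,
#'   `residual`, `stability`, `eigenvalues`).  Returns an empty list with a
#'   warning if no start converges.
#' @export
find_fixed_points <- function(model, guesses = NULL, tolerance = 1e-8,
                              order = 1, lattice_points = 4) {
  stopifnot(inherits(model, "fracomm_model"))
  N <- model$n_species
  f <- model_rhs(model, validate = FALSE)
  fn <- function(x) f(0, x)
  scale <- model_scale(model)
  starts <- list(rep(0, N))
  for (i in seq_len(N)) {
    e <- rep(0, N)
    e[i] <- scale[i]
    starts[[length(starts) + 1L]] <- e
    dom <- rep(0.02 * mean(scale), N)
    dom[i] <- scale[i]
    starts[[length(starts) + 1L]] <- dom
  }
  for (frac in c(0.25, 0.5, 1)) {
    starts[[length(starts) + 1L]] <- frac * scale
  }
  if (!is.null(model$groups)) {
    for (lab in model$groups$labels) {
      v <- rep(1e-3 * mean(scale), N)
      v[model$groups$members[[lab]]] <- mean(scale)
      starts[[length(starts) + 1L]] <- v
    }
  }
  if (N <= 3) {
    ax <- seq(0, 1.5 * max(scale), length.out = lattice_points)
    grid <- as.matrix(expand.grid(rep(list(ax), N)))
    starts <- c(starts, lapply(seq_len(nrow(grid)), function(i) grid[i, ]))
  }
  if (model$type == "glv") starts <- c(starts, glv_subset_solutions(model))
  if (!is.null(guesses)) {
    if (is.matrix(guesses)) {
      guesses <- lapply(seq_len(nrow(guesses)), function(i) guesses[i, ])
    }
    starts <- c(starts, lapply(guesses, as.numeric))
  }
  roots <- list()
  for (s in starts) {
    if (any(!is.finite(s)) || any(s < 0)) next
    res <- newton_root(fn, s, tol = tolerance)
    if (!isTRUE(res$converged)) next
    dup <- any(vapply(roots, function(r) {
      sqrt(sum((r$state - res$root)^2)) < 1e-6
    }, logical(1)))
    if (!dup) {
      roots[[length(roots) + 1L]] <- list(state = res$root,
                                          residual = res$residual)
    }
  }
  if (length(roots) == 0L) {
    warning("no fixed point found from any starting guess")
    return(list())
  }
  lapply(roots, function(r) {
    cl <- classify_stability(model, r$state, order = order)
    structure(list(state = r$state, residual = r$residual,
                   stability = cl$stability, eigenvalues = cl$eigenvalues),
              class = "fracomm_fixed_point")
  })
}

#' @export
print.fracomm_fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point (%s): [%s]  residual %.2e\n", x$stability,
              paste(format(x$state, digits = 4), collapse = ", "),
              x$residual))
  invisible(x)
}

# typical abundance scale used for search ranges
model_scale <- function(model) {
  p <- model$params
  switch(model$type,
    gonze = p$b / p$k,
    glv = {
      d <- diag(p$K)
      s <- ifelse(d < 0, -p$b / d, NA)
      s[!is.finite(s) | s <= 0] <- max(1, abs(p$b))
      s
    },
    logistic = p$C
  )
}

# exact fixed-point candidates of the gLV model: for every species subset,
# solve the restricted linear system b_S + K_SS x_S = 0
glv_subset_solutions <- function(model) {
  N <- model$n_species
  if (N > 12) return(list())
  p <- model$params
  out <- list()
  for (mask in seq_len(2^N - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(N) - 1)) > 0)
    sol <- tryCatch(solve(p$K[sel, sel, drop = FALSE], -p$b[sel]),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)) || any(sol <= 0)) next
    x <- rep(0, N)
    x[sel] <- sol
    out[[length(out) + 1L]] <- x
  }
  out
}

#' Classify the local stability of a fixed point
#'
#' Computes the eigenvalues \eqn{\lambda} of the finite-difference Jacobian
#' at the fixed point and applies the Matignon criterion for commensurate
#' Caputo systems of order \eqn{\mu}: the point is asymptotically stable iff
#' \eqn{|\arg\lambda| > \mu\pi/2} for every eigenvalue.  At \eqn{\mu = 1}
#' this reduces to the classical criterion \eqn{Re(\lambda) < 0}.  The label
#' is `"undetermined"` when any eigenvalue lies within tolerance of the
#' stability boundary or of zero (singular linearization).  Stability under
#' incommensurate orders is not classified.
#'
#' @param model a `fracomm_model`.
#' @param fixed_point state vector or `fracomm_fixed_point`.
#' @param order common derivative order \eqn{\mu} in (0, 1].
#' @param boundary_tol angular/magnitude tolerance for "undetermined".
#' @return list with `stability` (`"stable"`, `"unstable"`,
#'   `"undetermined"`) and `eigenvalues`.
#' @export
classify_stability <- function(model, fixed_point, order = 1,
                               boundary_tol = 1e-6) {
  if (inherits(fixed_point, "fracomm_fixed_point")) {
    fixed_point <- fixed_point$state
  }
  x <- as.numeric(fixed_point)
  if (!is.finite(order) || order <= 0 || order > 1) {
    stop("order must be in (0, 1]")
  }
  f <- model_rhs(model, validate = FALSE)
  J <- num_jacobian(function(z) f(0, z), x)
  ev <- eigen(J, only.values = TRUE)$values
  list(stability = matignon_label(ev, order, boundary_tol), eigenvalues = ev)
}

matignon_label <- function(eigenvalues, order, boundary_tol = 1e-6) {
  ev <- as.complex(eigenvalues)
  if (any(Mod(ev) < boundary_tol)) return("undetermined")
  margin <- abs(Arg(ev)) - order * pi / 2
  if (any(abs(margin) < boundary_tol)) return("undetermined")
  if (all(margin > 0)) "stable" else "unstable"
}

#' Canonical 15-species three-group community
#'
#' The package's standard structured testbed: three groups of five species
#' (blue, red, green) with weak within-group inhibition (`intra_K = 1`) and
#' strong between-group inhibition (`inter_K = 0.1`), growth rate
#' `b = 0.5`, death rate `k = 1`, Hill coefficient 2, and 5\% seeded
#' multiplicative noise on the interaction constants.  Group-level
#' tristability: each stable state is dominated by one group.  Basin
#' experiments on this community start from low-abundance initial
#' conditions (see [basin_sample()]), emulating assembly from rarity --
#' the regime in which memory imposed on one group shifts the stability
#' landscape against it.
#'
#' @param noise_amplitude relative noise on interaction constants.
#' @param seed seed for the interaction-constant noise.
#' @return A `fracomm_model` with a blue/red/green [group_structure()].
#' @export
three_group_community <- function(noise_amplitude = 0.05, seed = 7) {
  build_group_model(c(5L, 5L, 5L), intra_K = 1, inter_K = 0.1, hill_n = 2,
                    b = 0.5, k = 1, noise_amplitude = noise_amplitude,
                    seed = seed)
}
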