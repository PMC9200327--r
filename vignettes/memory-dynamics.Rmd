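---
title: "Modeling ecological memory in microbial community dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ecological memory in microbial community dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracomm)
```

## The model family and what "memory" means here

Standard community models of the generalized Lotka-Volterra (gLV) family
are memoryless: the rate of change of each species' abundance depends only
on the current state.  `fracomm` studies what changes when a community's
dynamics instead carry *long-term ecological memory* -- a dependence of the
present rate of change on the entire past trajectory, with influence
decaying as a power law.  Such memory is plausible wherever community-level
inertia emerges from phenotypic heterogeneity, dormancy, or slow
environmental feedback.

Formally, the first-order time derivative of each species is replaced by a
Caputo fractional derivative of order $\mu_i \in (0, 1]$:

$$D^{\mu_i} X_i = F_i(t, X), \qquad
F_i = X_i\left(b_i f_i(\{X_k\}) - k_i X_i\right) \;\text{or}\;
X_i\Big(b_i + \sum_j K_{ij} X_j\Big),$$

where the first form is the Hill-inhibition ("Gonze-type") model
($f_i = \prod_{k \ne i} K_{ik}^n / (K_{ik}^n + X_k^n)$) and the second the
pairwise gLV.  Equivalently, $dX_i/dt$ equals a convolution of $F_i$ with a
power-law kernel: at $\mu_i = 1$ the kernel degenerates to a Dirac delta
(the classical, memoryless system), and for $\mu_i < 1$ past states
influence the present with weight decaying as a power law of their age.  We
quantify **memory strength** as $1 - \mu_i$.  Orders may differ between
species (*incommensurate* memory) or be shared (*commensurate*).

A single-species logistic model ($rX(1 - X/C)$) is included as the minimal
illustration: memory stretches its approach to the carrying capacity from
exponential to algebraic.

## The solver

`caputo_solve()` implements the fractional Adams-Bashforth-Moulton
predictor-corrector (P(EC)$^m$) on a uniform grid.  The memory integral is
discretized with the fractional rectangle rule (predictor) and fractional
trapezoid rule (corrector); `caputo_weights()` exposes the quadrature
weights, which reduce exactly to the classical rectangle/trapezoid weights
at $\mu = 1$.  Design points:

* **Incommensurate orders.** Each species keeps its own weight sequence and
  its own history convolution; the scheme treats every equation with its
  own $\mu_i$, which is exactly how the per-species formulation is stated.
* **Cost.** The convolution over the full history is quadratic in the step
  count.  Species at $\mu_i = 1$ are detected and integrated with running
  sums (linear cost), so memoryless baselines are cheap.  An optional
  `history_window` truncates the convolution to the most recent nodes --- a
  clearly flagged short-memory approximation, off by default; with a window
  covering all steps it reproduces the full-history solution exactly.
* **Time-dependent right-hand sides.** Perturbation schedules enter by
  evaluating $F$ at each node's own time; the kernel weights are untouched.
* **Non-negativity.** Abundances within `negative_floor` (default 1e-12)
  below zero are clamped to zero; anything lower aborts with the failing
  time, because large negative excursions indicate a step-size
  misconfiguration rather than dynamics.  Predictor overshoot below zero is
  truncated for the $F$-evaluation only.
* **Grid conventions.** If the horizon is not an integer multiple of the
  step, the grid runs one step past it and the final state is linearly
  interpolated at the horizon --- the same linear interpolation
  `trajectory_state()` uses for any off-grid query.  Interpolation order
  below the solver's order does not degrade the reported metrics at the
  default steps.
* **Corrector passes.** One pass by default (`corrector_iterations = 1`);
  the accepted state is re-evaluated so the stored history holds
  $F(t_{n+1}, X_{n+1})$.

### Accuracy

On $D^\mu X = -X$, $X(0) = 1$ the solver is validated against the
Mittag-Leffler closed form $E_\mu(-t^\mu)$: with $h = 0.005$ on $t \in
[0, 5]$ the maximum absolute error is about $5\times10^{-4}$ at $\mu = 0.5$
and $1.5\times10^{-6}$ at $\mu = 1$.  Empirical convergence orders measured
at the endpoint rise from about 1.45 at $\mu = 0.3$ toward 2 at $\mu = 1$,
matching the scheme's theoretical $\min(2, 1+\mu)$ behavior.  Note a known
property of this scheme: the solution's $t^\mu$ start-up behavior limits
the *sup-norm* rate over grids that include $t \approx 0$, so convergence
order is assessed at fixed time.  With all $\mu_i = 1$ the solver agrees
with an independent high-accuracy classical integrator (`deSolve::lsoda`)
to better than $10^{-4}$ sup-norm over 100 time units on every bundled
model.

### The Mittag-Leffler oracle

`mittag_leffler()` exists to validate the solver, so it refuses to return
uncertified values.  It combines a Kahan-compensated power series (log-space
terms, cancellation-aware error bound) with the algebraic asymptotic
expansion for large negative arguments (optimally truncated, plus the
decaying oscillatory exponential for orders in (1, 2)); $\mu = 1, 2$ reduce
to `exp` and `cosh`/`cos`.  Where neither route certifies $10^{-10}$
relative accuracy -- a narrow band of moderately large negative arguments --
it signals `unsupported-domain` instead of degrading silently.

## Perturbations

Growth-rate schedules are declarative timelines over base parameter values:

* **Pulses** replace a rate by a fixed value on half-open windows
  $[t_\text{on}, t_\text{off})$; the half-open convention avoids double
  definition at boundaries.  Overlapping segments for the same
  species/parameter are rejected.
* **Alternating** schedules tile a window with low/high half-cycles.
* **Stochastic** forcing uses an Ornstein-Uhlenbeck process sampled with
  its *exact* Gaussian transition (no Euler discretization error), seeded
  and reproducible; the path enters the solver as a piecewise-constant
  modulation on the solver grid, keeping the fractional quadrature
  well-defined.  Negative growth-rate excursions are floored at zero and
  counted.  Defaults ($\theta = 1$, $m =$ base rate, $\sigma = 0.1\,m$) are
  pragmatic, config-overridable choices.

## Metrics

* **Bray-Curtis dissimilarity** on absolute abundances,
  $\sum_i |X_{i,1} - X_{i,2}| / \sum_i (X_{i,1} + X_{i,2})$, is the
  distance underlying all convergence notions (this is the printed formula;
  relative abundances are *not* used here).
* **Convergence time** is the first entry into the "convergence interval"
  (Bray-Curtis at or below a threshold) with an optional dwell requirement;
  dwell 0 (first crossing) is the default, the dwell window existing
  because trajectories can briefly graze an interval near a saddle.
* **Recovery time** is convergence time restricted to after a
  perturbation's end, reported relative to it.
* **Resistance** is the strongest pulse a community withstands while still
  returning to its initial stable state; `resistance_threshold()` bisects
  the pulse strength, verifies the outcomes at both bracket ends, and
  returns a flagged result (rather than an error) when a scenario has no
  threshold in range, which is the expected answer for monostable systems
  or when memory suppresses the shift entirely.
* **Recovers vs shifts** is decided by which candidate state's convergence
  interval the post-pulse trajectory enters *first*, within a horizon
  several times the memoryless convergence time -- memory slows dynamics,
  so decision horizons must scale with it.  Exact dominance ties raise an
  error instead of being broken silently: they are measure-zero and
  indicate a degenerate setup.

## Study conditions and how the scenarios were designed

All experiments run on model-generated trajectories; no external data is
needed.  The parameter sets below are the package's fixed study conditions.
They are qualitative stand-ins chosen once and verified by the test suite
(the classifier confirms the claimed multistability at run time), not fits
to any external dataset.

* **Symmetric 3- and 2-species communities** (`symmetric_gonze_model()`):
  $b = k = 1$, $K_{ij} = 0.1$, $n = 2$.  Three stable single-species-
  *dominant* states for three species (the suppressed species persist at
  low abundance ~0.010 because an absent species always has positive
  per-capita growth $b f_i$; the exclusion states $(1,0,0)$ etc. exist but
  are unstable); two such states for two species.  The interior symmetric
  state is unstable.
* **Resistance scenario**: from the species-1-dominant state, the pulse
  sets $b_1$ to a value $s$ on $[20, 120)$; resistance is reported as the
  withstood depth $1 - s^*$.  The 100-unit window leaves the critical
  strength interior for every tested memory value; with shorter pulses,
  memory 0.2+ withstands *any* strength (the flagged no-threshold case).
* **Recovery time-scale reversal**: a short displacing pulse ($b_1 = 0.05$
  on $[20, 30)$).  The loose interval is Bray-Curtis 0.02.  In this
  parameterization the crossover between memory-hastened and
  memory-slowed recovery sits near Bray-Curtis $5\times10^{-4}$, so the
  tight interval is placed a decade below it at $10^{-4}$, where it
  measures the late power-law stage; a tight interval placed at the
  crossover would measure neither regime.
* **Hysteresis**: a strong opposite-direction pulse pair.  Because Hill
  inhibition bounds an invader's per-capita growth at $b f \sim 10^{-4}$,
  raising a suppressed species' rate cannot flip this community; the
  opposite pulses therefore act as ($b_1$ down + $b_2$ up), then $b_2$
  down.  The second pulse is near-critical ($b_2 = 0.47$), where the
  memoryless community crawls past the saddle while the community with
  memory -- less committed to the alternative state and with most of its
  history at the original one -- crosses back quickly.  Return is measured
  at the state-shift interval (Bray-Curtis 0.2); at tighter intervals the
  fractional power-law tail of the final approach dominates and masks the
  basin-crossing effect.  For slightly stronger second pulses the
  memoryless community never returns at all while the memory community
  does.
* **Stochastic damping**: independent seeded OU forcing on all three
  growth rates, equal initial abundances (0.5 each), analysis window of
  200 time units -- about twice the memoryless convergence time, so it
  covers the memoryless collapse to dominance and its aftermath.  The
  time-averaged abundance variance is averaged over three replicate
  forcings per memory level; single paths can tie when neither community
  has yet broken symmetry.
* **15-species three-group community** (`three_group_community()`): groups
  blue/red/green of five species, within-group $K = 1$, between-group
  $K = 0.1$ (between-group inhibition stronger), $b = 0.5$, $k = 1$, 5%
  seeded noise on interaction constants.  Basin experiments draw initial
  conditions uniformly on $(0, 0.01]$ -- community assembly from rarity,
  well below the inhibition threshold $K = 0.1$.  In this regime the
  outcome is a growth race, and a group with memory races at the effective
  exponential rate $b^{1/\mu} < b$ (for $b < 1$): imposing memory 0.2 on
  the blue group cuts its share of dominant outcomes from roughly a third
  to nearly zero, after a characteristic temporary early rise.  The
  direction of this effect is regime-dependent: starting from
  near-equilibrium abundances instead, the memory group's slower
  post-peak decline keeps inhibiting its competitors and memory then
  *favors* it -- memory in a species may help or harm it depending on
  context, and the package makes both regimes reproducible.  Basin runs
  use 20 draws per condition; the directional contrast is stable across
  master seeds at this size.
* **Bifurcation scans** read compositions exactly at the horizon (1,000
  time units), not at convergence, because long transients are part of
  the signal: just outside the multistable region, a strongly
  memory-laden community started near the vanished ("ghost") state is
  still there at the horizon while every memoryless run has long settled
  into the unique stable state.
* **Memory-threshold search** bisects the common memory strength of a
  target species set between two dominance outcomes, all other species
  memoryless, verifying the outcomes at both bracket ends.  On the
  bundled stand-in community the blue-group threshold for a typical
  flipping initial condition lands around 0.08--0.17 depending on the
  initial condition; reproducing any particular published threshold value
  requires the exact originating model specification, which is not
  bundled.
* **Coexistence slowdown**: the monostable two-species gLV pair with one
  positive and one negative interaction ($b = (1, 1)$, $K_{11} = K_{22} =
  -1$, $K_{12} = 0.4$, $K_{21} = -0.6$; stable interior state near
  $(1.13, 0.32)$) shows convergence time to the coexistence state rising
  monotonically with commensurate memory -- the bare "inertia" effect with
  no competing attractor involved.

### Problem sizes

Default test and acceptance runs use steps of 0.05--0.1 time units and
horizons of 150--2,500 units (up to 50,000 grid nodes), 20 basin draws per
condition, three OU replicates, and bisection tolerances of 0.01--0.02 in
memory strength or pulse strength and 2% of the pulse range for
resistance.  All are package choices balancing quadratic solver cost
against the scales of the phenomena; each can be raised through the same
interfaces.

## Fixed points and stability

`find_fixed_points()` runs projected damped Newton iterations from a
structured multi-start set (origin, single-species states, dominance
patterns, uniform states, a coarse lattice for up to three species, and
exact subset solutions for gLV), deduplicates by Euclidean distance, and
classifies each root by the **Matignon criterion**: a fixed point of a
commensurate order-$\mu$ system is asymptotically stable iff every
eigenvalue $\lambda$ of the local linearization satisfies
$|\arg \lambda| > \mu \pi / 2$.  At $\mu = 1$ this is the classical
criterion; lowering $\mu$ widens the stable sector, so classical stability
is never lost by adding commensurate memory.  Eigenvalues within tolerance
of the sector boundary or of zero yield `"undetermined"`.  Stability under
*incommensurate* orders is deliberately not classified -- such systems lack
an equally simple criterion and are assessed by simulation.

## What the synthetic conditions do and do not emulate

The generators emulate the structural features the theory needs:
multistability with basins of attraction, group-structured competition,
parameter noise, pulse/periodic/stochastic forcing of growth rates.  They
do not emulate measurement noise, sampling depth or compositionality of
real sequencing data, demographic stochasticity, immigration, or
time-varying interaction topologies.  Passing tests therefore demonstrate
properties of the *models* under memory, not the detectability of memory
in empirical time series, and say nothing about parameter inference --
fitting interaction coefficients to data is explicitly out of scope (the
empirically parameterized gLV is supported structurally; its published
coefficients are user-supplied inputs).

## Known limitations

* Fractional orders above 1, distributed or time-varying orders, and
  delay-differential formalisms are not supported.
* The full-history solver is quadratic in step count; the short-memory
  window trades accuracy for speed and is not used in any shipped result.
* The Mittag-Leffler evaluator refuses a narrow argument band it cannot
  certify (see above).
* Near-threshold scenario outcomes (resistance, hysteresis) depend on step
  size at the percent level; bisection tolerances are chosen coarser than
  that dependence.
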