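# fracomm

Simulation and analysis of interacting microbial communities whose
dynamics carry long-term **ecological memory** — a dependence of the
present rate of change on the community's entire past trajectory, with
power-law decaying influence.

Memory is introduced by replacing the first-order time derivatives of
generalized Lotka-Volterra-family models with **Caputo fractional
derivatives** of per-species order μ<sub>i</sub> ∈ (0, 1]:

    D^{μ_i} X_i = F_i(t, X)

with `F_i = X_i (b_i f_i − k_i X_i)` for the Hill-inhibition
("Gonze-type") community model, `f_i = Π_{k≠i} K_ik^n / (K_ik^n + X_k^n)`,
or `F_i = X_i (b_i + Σ_j K_ij X_j)` for the pairwise gLV. At μ = 1 the
classical memoryless model is recovered exactly; **memory strength** is
defined as 1 − μ<sub>i</sub>, and species may have distinct orders
(*incommensurate* memory).

The package is aimed at theoretical/microbial ecologists who want to ask:
what does memory do to multistability, to resistance and resilience
against pulse, periodic and stochastic perturbations, and to the
transient behavior of community assembly?

## What's inside

- **Solver** — a fractional Adams–Bashforth–Moulton predictor-corrector
  (`caputo_solve()`, compiled core) supporting incommensurate orders,
  time-dependent growth rates, optional short-memory truncation, and a
  fast linear-cost path for memoryless species; validated against
  Mittag-Leffler closed forms (`mittag_leffler()`) and an independent
  classical integrator.
- **Models** — Hill-inhibition communities (2, 3, or group-structured 15
  species), pairwise gLV, logistic; fixed-point search and stability
  classification by the Matignon criterion (`find_fixed_points()`,
  `classify_stability()`).
- **Perturbations** — pulse, alternating, and exact-discretization
  Ornstein–Uhlenbeck growth-rate schedules (`pulse_timeline()`,
  `alternating_timeline()`, `simulate_ou()`).
- **Metrics** — Bray–Curtis dissimilarity, convergence and recovery
  times, resistance thresholds by verified bisection (`bray_curtis()`,
  `convergence_time()`, `recovery_time()`, `resistance_threshold()`).
- **Experiments** — bifurcation scans, seeded basin-of-attraction
  sampling, memory sweeps, and memory-threshold searches
  (`bifurcation_scan()`, `basin_sample()`, `memory_sweep()`,
  `memory_threshold_search()`).
- **CLI / configs** — JSON scenario configs (`load_config()`,
  `run_scenario()`) and an `exec/fracomm` command-line driver with
  `simulate`, `basin`, `scan` and `threshold` verbs.

## Worked example

Three mutually inhibiting species (b = k = 1, K = 0.1, n = 2) form a
tristable community; memory slows convergence to the stable state:

```r
library(fracomm)

community <- symmetric_gonze_model(3)
stable <- Filter(function(f) f$stability == "stable",
                 find_fixed_points(community))
for (f in stable) print(f)
#> Fixed point (stable): [0.97947, 0.01021, 0.01021]  residual 5.02e-12
#> Fixed point (stable): [0.01021, 0.97947, 0.01021]  residual 5.02e-12
#> Fixed point (stable): [0.01021, 0.01021, 0.97947]  residual 5.02e-12

target <- stable[[1]]$state
spec <- convergence_spec(reference = target, threshold = 0.02)
for (mem in c(0, 0.1, 0.2)) {
  traj <- simulate_model(community, orders = 1 - mem,
                         initial_state = c(0.8, 0.1, 0.1),
                         settings = solver_settings(step_size = 0.05,
                                                    horizon = 1500))
  cat(sprintf("memory %.1f: convergence time %.2f\n", mem,
              convergence_time(traj, spec)))
}
#> memory 0.0: convergence time 107.40
#> memory 0.1: convergence time 317.90
#> memory 0.2: convergence time 1127.95
```

The three stable states are each dominated by one species (the others
persist at low abundance — strict exclusion states exist but are
unstable). A memory strength of 0.2 stretches the time to re-enter the
Bray–Curtis 0.02 interval around the stable state by an order of
magnitude: the signature inertia of power-law memory.

The same machinery quantifies the headline perturbation effects: memory
*increases resistance* (a community with memory withstands deeper
growth-rate pulses before shifting state), *hastens early recovery but
slows its late stages* (loose vs tight convergence intervals), *mitigates
hysteresis* under opposite pulse pairs, *damps* stochastically forced
abundance fluctuations, and *shifts basins of attraction* against a
species group that carries memory. See the methods vignette
(`vignettes/memory-dynamics.Rmd`) for the models, scenario designs and
numerical choices.

## Command-line usage

```sh
exec/fracomm simulate --config scenario.json --out results/
```

where `scenario.json` declares model, memory, solver, perturbation and
experiment sections; see `load_config()` for the schema. Logs go to
stderr, data to `--out`, and exit codes are 0/1/2 for ok / user error /
internal error.
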