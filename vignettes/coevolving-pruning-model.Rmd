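---
title: "A co-evolving attractor network model of synaptic pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A co-evolving attractor network model of synaptic pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synprune)
```

## The model

`synprune` simulates an Amari-Hopfield attractor network whose synaptic graph
is itself dynamic. Two processes run on different clocks and feed back into
each other.

**Neural dynamics.** Each of the `N` neurons is binary, `s_i ∈ {0,1}`. Given
an adjacency `e_ij` and Hebbian couplings

    w_ij = [κ∞ a0 (1 − a0)]⁻¹ Σ_μ (ξ_i^μ − a0)(ξ_j^μ − a0),

storing `P` binary patterns `ξ^μ` with mean activity `a0`, neuron `i` feels
the local field `h_i = Σ_j w_ij e_ij s_j`, is gated by the threshold
`θ_i = ½ Σ_j w_ij e_ij`, and all states are updated synchronously with

    P{s_i = 1} = ½ [1 + tanh(2β (h_i − θ_i))],   β = 1/T.

The factor 2 makes this the heat-bath rule for the equivalent ±1 spins
(whose local field is `2(h_i − θ_i)`); under this temperature convention the
fully connected reference network with one balanced pattern has its
continuous retrieval transition at the canonical `T = 1`, which is the scale
on which all temperatures in the package are quoted. Retrieval is measured
by the overlap `m^μ = (N a0 (1 − a0))⁻¹ Σ_i (ξ_i^μ − a0) s_i`. `T = 0` is
implemented as an explicit sign rule with a fair coin on exact ties, rather
than a large `β`, to avoid overflow.

**Structural dynamics.** Every `h_s` sweeps (default 10) the graph is
updated once. Global probabilities

    u(κ) = (n/N)(1 − κ/2κ∞),    d(κ) = (n/N) κ/2κ∞

set the numbers of created and destroyed edges (Poisson with means `Nu`,
`Nd`), so the mean degree relaxes as
`κ(t) = (κ0 − κ∞) e^{−t/τ_p} + κ∞` with `τ_p = N κ∞ / 2n` — the
exponential synaptic-pruning curve. Which node gains or loses is decided by
local probabilities driven by the incoming current `I_i = |h_i − θ_i|`:

    π(I_i) = 2 I_i^α / (⟨I^α⟩N) − 1/N,
    η(I_i, k_i) = 2 I_i^γ / (⟨I^γ⟩N) − k_i/(κN),

clipped at zero and renormalised. A gain selects a node by `π`, then wires
it to a uniformly chosen non-neighbour; a loss selects a node by `η` and
removes a uniformly chosen incident edge. Together with these uniform
second-node channels the *effective* per-node weights are
`π̃ = ½(π + 1/N) ∝ I^α` and `η̃ = ½(η + k/(κN)) ∝ I^γ` when no clipping is
active. Selecting nodes directly by `π̃`/`η̃` would double-count the uniform
channels and suppresses the preferential attachment — an easy trap we
verified numerically (the critical topological state then never becomes
scale-free).

In the **topological limit** the currents are replaced by the degrees,
`I_i → k_i`, decoupling structure from activity. The degree distribution
then obeys a one-step master equation, integrated by
`integrate_master()` / `stationary_distribution()` with explicit Euler steps
bounded by the fastest rate. Two rate variants are exposed:

* `rates = "powerlaw"` (default): the literal master-equation rates, with
  effective weights proportional to `k^α` and `k^γ` and the uniform
  random-partner channel kept as a floor so `k = 0` is not absorbing;
* `rates = "mc"`: the exact mean-field image of the simulation's clipped,
  renormalised selection (with saturated nodes excluded as the sampler
  resamples them). This is the variant to use when validating the
  integrator against Monte Carlo runs. At the critical point `α = γ = 1`
  the literal rates give a stationary tail exponent ≈ 2.65 (N = 3200, MLE
  for `k ≥ κ∞`), close to the literature value ≈ 2.5, while the
  MC-faithful variant is measurably steeper: the clipping renormalisation
  carries a weight excess at criticality that imposes a weak geometric
  cutoff on the tail.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `N` | neurons | 800–3200 | finite-size effects are strong below 800 |
| `T` | noise level | — | reference transition at `T = 1` |
| `alpha`, `gamma` | current-exponents of gain/loss | `gamma = 1` | `γ = 1` makes edge removal uniform per edge; `α/γ` decides homogeneous vs heterogeneous structure (critical at `α = γ`) |
| `n` | edges rewired per structural step | 10 (phase lines: 5) | sets the pruning speed only |
| `h_s` | sweeps per structural step | 10 | separation of neural and structural clocks |
| `kappa_inf` | stationary mean degree | 10 | adult synaptic density |
| `kappa0` | initial mean degree | `2 kappa_inf` for pruning runs; `kappa_inf` for phase-diagram runs | see below |
| `a0` | pattern activity | 0.5, or `1/P` for sparse memories | |

`kappa0` deserves a note. Developmental (pruning and capacity) runs start
overgrown, `κ0 = 2κ∞`, matching the roughly two-fold density decline seen
in cortical data. Phase-diagram and bistability experiments instead start
at `κ0 = κ∞`: an overgrown start makes the early network retrieve at noise
levels where the stationary one cannot (the retrieval temperature grows
with `κ`), so the transient itself would nucleate the memory branch and
mask the homogeneous noisy phase.

## What the experiments show — and their limits at desk scale

The package reproduces, at `N = 800–3200`:

* the reference Hopfield transition at `T = 1.0 ± 0.1`
  (`hopfield_transition_scan()`);
* the exponential pruning curve with `τ_p = Nκ∞/2n` in every mode;
* the three stationary phases of the topological limit and the scale-free
  critical state at `α = γ`, with Monte Carlo and master-equation degree
  distributions agreeing to total-variation distance ~0.01 in the
  homogeneous and critical phases;
* memory–structure feedback: in the retrieval state the current–degree
  correlation exceeds 0.9, and collapses in the noisy state;
* bistability of the coupled model at high `α`, `T`: heterogeneous initial
  topologies settle in a heterogeneous, strongly disassortative memory
  state while homogeneous ones stay homogeneous and noisy — and the
  initial-condition dependence disappears in the topological limit.

Known quantitative limitations, all documented deliberately rather than
worked around:

* **Supercritical mean-field breakdown.** For `α > γ` the simulation
  condenses into a frozen, nearly bipartite hub state (every bulk node
  attached only to saturated hubs). This degree–degree correlation is
  outside any single-site master equation, so the total-variation agreement
  fails there (~0.7) even though both routes agree on the homogeneity
  `g → 0`.
* **Structural equilibration is slow.** The degree-distribution tail
  equilibrates on ~100 τ_p, far beyond the κ-relaxation. Critical-line
  runs therefore use the heterogeneous initial condition (the attractor on
  that line; homogeneous starts converge to the same statistics roughly an
  order of magnitude more slowly) and 10 τ_p horizons with stationarity
  drift checks.
* **Neighbour-degree and clustering decays are shallower than published.**
  At the desk-scale critical point we measure `k_nn(k) ~ k^-0.4` against a
  published exponent near 1, and the clustering spectrum shows a
  comparable shortfall. Both deepen toward
  the published values only inside the bimodal phase, where hub–leaf
  condensation correlations develop; with uniformly chosen partners the
  `k_nn` of a hub is floored at ⟨k⟩, so strong decay requires exactly the
  condensation that a near-critical finite system has not yet built.
* **Sparse-pattern capacity.** With `a0 ≈ 1/P` the current `I = |h − θ|`
  is as large for deeply silent as for firing neurons, so structural growth
  condenses onto never-active nodes and no pattern-specific scaffold forms;
  recovered-pattern overlaps saturate near 0.4 for `P ≥ 10`
  (high-retrieval capacity stops at `P ≈ 3`), far below published
  capacities (`P > 50`). We verified this across initial densities
  (`κ0` up to `16 κ∞`), stationary degrees (`κ∞` of 10 and 40), overlapping
  and disjoint active blocks, the `η → η(I)` approximation, and horizons up
  to 100 τ_p. Reproducing the published capacity appears to require either
  much denser networks or a growth rule that distinguishes firing from
  silent high-|current| neurons.

## Numerical choices

* All randomness flows through R's RNG; a `sim_config(seed =)` fixes a run
  byte-for-byte. The structural sampler uses cumulative-weight
  (rejection-free) selection; infeasible draws (saturated or isolated
  nodes) are resampled a bounded number of times, then counted as skipped.
* Gains and losses within one structural step execute in random interleaved
  order to avoid ordering bias at large `n`.
* Currents entering the structural step are taken from the last sweep of
  the preceding neural window (`current_window = "average"` switches to the
  window mean).
* A fully silent network (all `I = 0`) falls back to uniform gains and
  degree-proportional losses.
* The master-equation integrator conserves normalisation to round-off
  (the equation telescopes), guards positivity by step halving, and
  declares stationarity at `‖dp/dt‖₁ < 10⁻⁹`.
* Power-law tails are fitted by discrete maximum likelihood on the bounded
  support, with the lower cutoff either fixed (critical-phase fits use
  `k_min = κ∞`) or chosen by Kolmogorov–Smirnov minimisation; a mass-
  weighted log-binned least-squares slope is available as a cross-check.
  Spectra (`k_nn(k)`, `C(k)`) are fitted by weighted log–log regression.
* Density-curve fits use Levenberg–Marquardt least squares with multi-start
  over decade-spaced time constants, because the two-exponential
  (growth-factor) model is ill-conditioned when `τ_g ≈ τ_p`.

## What the synthetic data do and do not emulate

All test inputs are generated in code: pattern sets, initial degree
sequences (regular, or discrete power-law with the cutoff tuned to the
requested mean), and density series from the closed forms with
multiplicative Gaussian noise. The density generator emulates the shape and
noise scale of developmental synaptic-density measurements but none of
their systematic effects (sampling by subject age, layer-to-layer
variability, counting biases), so passing fits demonstrate parameter
recovery, not biological validity. Likewise the network generator produces
uncorrelated graphs with prescribed degree sequences; real cortical
networks carry spatial and correlational structure that the model itself is
meant to *produce*, not presuppose.

## A short example

```{r, eval = FALSE}
cfg <- sim_config(N = 800, T = 0.8, alpha = 1, gamma = 1,
                  kappa_inf = 10, kappa0 = 20, mode = "coupled",
                  neural_init = "pattern", t_max = 4000, seed = 1)
run <- run_coevolution(cfg)
stationary_average(run$trajectory, cfg$t0_avg, cfg$dt_avg)
kappa_trajectory_check(run)   # sup-norm deviation from the pruning curve
```
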