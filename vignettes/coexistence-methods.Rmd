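---
title: "Methods: competition models with positive density-dependent mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competition models with positive density-dependent mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdd)
```

# The model and its assumptions

All systems in this package are rescaled Lotka–Volterra competition models:
densities are measured relative to carrying capacity, time relative to the
intrinsic growth rate. Consequently every rate parameter is dimensionless
and `d`, the basal mortality rate, is a fraction of the growth rate
(`d ∈ [0, 1]`; at `d = 1` a lone rare species cannot grow at all).

The distinctive ingredient is a mortality term `d · D(n)` whose multiplier
declines with conspecific density:

$$D(n) = \frac{1}{1 + s\,n}, \qquad D'(0) = -s .$$

`s` is the *density-dependence factor*: the decline rate of mortality at
vanishing density. `s = 0` recovers constant mortality (plain
Lotka–Volterra). The hyperbolic form has two properties that drive all
results:

* $\partial D/\partial n < 0$ everywhere — positive density dependence at
  all densities;
* $\partial D/\partial s = -n/(1+sn)^2$ is *unimodal* in `n` (maximal
  magnitude at `n = 1/s`): raising `s` barely changes the mortality of an
  abundant species but greatly reduces that of a moderately rare one. This
  is why stronger positive density dependence can *favor* the rarer, less
  competitive species and create coexistence equilibria instead of
  destroying them.

For `s > 100`, mortality is strongly reduced even at very low density, so
density feedback is nearly flat over most of the density range; maps are
conventionally split at `s = 100` when displayed, and the canonical scan
grid (`canonical_s_grid()`) spans `{0} ∪ [10⁻², 10⁴]` on a log scale.

Species are otherwise symmetric (same carrying capacity, same density
dependence); asymmetry enters through exactly one of three channels —
asymmetric competition `α1`, a basal-mortality difference `δ` (species 2
dies at `d + δ(1 − d)`, so `δ = 1` means certain decline even when alone),
or asymmetric reproductive interference `α1′`. Interference is
*frequency*-dependent: the growth factor `1/(1 + α1′ n1/n2)` depends on the
heterospecific:conspecific ratio, so however small the interfering
population, a sufficiently rare species is fully suppressed. This is the
mechanism behind the headline result that under reproductive interference
coexistence is only ever a local attractor.

## Mortality kinds and the registry

The exact alternative mortality functions used in supplementary analyses of
the source theory are not printed in its main text; the package therefore
ships a small registry (`register_mortality_kind()`) with `hyperbolic` as
the documented default plus three declared stand-ins: `exponential`
(`exp(−sn)`), `linear` (`max(0, 1 − sn)`), and a `density-independent-control`
that fixes the multiplier at its value at a reference density (`1/(1+s·c)`,
default `c = 1`) so that increased `s` still lowers mortality while density
feedback is switched off. All kinds reduce to `D ≡ 1` at `s = 0`, map into
`[0, 1]`, and (except the control) are normalized to `D'(0) = −s`, so `s`
means the same thing across kinds. New kinds can be registered at run time;
they are integrated by a pure-R fallback core (below).

# Equilibria and the tristate classification

* **Single species.** Nonzero equilibria of `1 − n − m·D(n) = 0` are
  computed in closed form for the hyperbolic kind (the quadratic
  `s n² + (1−s) n + (m−1) = 0`) and by bracketed `uniroot` otherwise. A
  nonzero root is stable iff the per-capita growth slope is negative there.
* **Two species.** Boundary equilibria come from the single-species roots;
  interior equilibria from damped Newton iteration on the per-capita system,
  started from a fixed 12×12 log-spaced seed grid over `(0, 1.5]²` and
  deduplicated at L∞ distance `1e-6`. Every reported equilibrium is
  re-verified to residual `max |dn/dt| < 1e-10`. The hyperbolic models have
  at most a handful of interior roots (the interior system reduces to
  quadratics), so this grid is generous; at `s = 0` the closed-form
  Lotka–Volterra solution is reproduced to `1e-8`, which is the same
  validation logic the source theory used for its numerical method.
* **Stability.** Jacobians are central finite differences with step
  `1e-7·max(1, |n_k|)` (one-sided at boundary zeros); locally stable means
  all eigenvalue real parts `< −1e-8`. Eigenvalues within `1e-8` of zero
  mark the record *marginal* and the classification *inconclusive* —
  bifurcation boundaries are measure-zero in the scanned planes, so we flag
  rather than guess.
* **Classification.** With a feasible locally stable interior equilibrium
  present, the label is `global_attractor` iff (a) every missing species has
  a positive invasion growth rate at every locally stable boundary
  attractor, and (b) trajectories started from the probe grid
  `{10⁻⁴, 10⁻², 10⁻¹, 0.5, 1}²` all converge (L∞ distance `< 1e-4`) to the
  interior equilibrium; otherwise `local_attractor`. Probe integrations
  disable extinction pruning — the classification concerns the continuous
  flow, not the bookkeeping threshold. Non-convergent probes within the time
  budget make the cell inconclusive, recorded as such and never
  interpolated.
* **Invasion rates** are evaluated in the exact zero-density limit: the
  interference growth term tends to 0 whenever an interfering resident has
  positive density, and to 1 otherwise; competition and mortality enter as
  `−Σ αj,i nj − m_i·D(0)`.
* **s-thresholds.** Class changes along `s` are refined by bisection in
  `log10 s` to relative tolerance `1e-3`; a change between `s = 0` and the
  first positive grid point is bisected down to `s = 1e-8` with the `s = 0`
  class as the left label. The analytic expression for these thresholds
  lives in unpublished supplementary material; this package locates them
  numerically only, validated by the hand-derivable special case quoted in
  the README (at `d = 0.9`, `α1 = 0.5` the global→none transition solves
  `α1·n1*(s) = 1 − d`).

# Numerical integration

No ODE solver package is assumed: the integrator is an adaptive
Dormand–Prince 5(4) scheme with FSAL and PI-free step control, implemented
in C++ (`src/integrate.cpp`), with an identical pure-R twin used as a
cross-check oracle in the tests and as fallback for registry-added mortality
kinds. Tolerances default to `rtol = 1e-10`, `atol = 1e-12`: positive
density dependence creates slow manifolds near the extinction threshold,
and loose tolerances would misclassify trajectories that creep along them.
The systems are smooth with O(1) eigenvalues, so an explicit embedded RK
pair at tight tolerance is the appropriate tool; near equilibria the step
size grows without bound, so long horizons are cheap.

Zero density is absorbing *exactly*: the derivative of a coordinate at 0 is
0 in every Runge–Kutta stage, so pruned species stay at 0 bitwise. The
printed interference term divides by `n_i`; it is evaluated in the
singularity-free form `n_i²/(Σ_j α′j,i n_j)`, algebraically identical for
`n_i > 0` and 0 at `n_i = 0`.

Simulations run in windows of length 1000; after each window, species below
the extinction threshold `1e-3` are set to exactly 0 (pruning is
bookkeeping, not event detection — the threshold's role in the source
theory). Convergence is declared when `max |dn_i/dt| < 1e-9` over
survivors; the total budget is `1e6` time units, after which the run is
flagged non-converged (a flag, not an error). "Long enough for transients
to dissipate" has no printed horizon in the source; this derivative
criterion substitutes for it.

# The synthetic species pools

`pool_config()`/`generate_pool()` emulate random pools drawn from uniform
distributions under four scenarios: (1) only asymmetric competition, (2)
only reproductive interference (competition symmetric at `α`, default 0),
(3) only basal-mortality differences (symmetric `α`, default 0.05), (4) all
asymmetries. The reference analyses used 500 pools × 100 species with
`d = 0.5` and those `α` defaults; the *bounds* of their uniform
distributions are in unpublished supplementary material, so the package
declares its own and exposes every range in the config:

* `comp_range = ri_range = U(0, 2/N)`. With N−1 competitors, this keeps the
  expected total interspecific pressure `Σ_{j≠i} E[α_{j,i}] ≈ 1`, the same
  order as self-limitation — the regime where richness outcomes are
  informative rather than trivially 0 or N. This choice was made once, on
  that argument, and not revisited.
* `delta_range = U(0, 1)`, the parameter's full domain.

Seeding is counter-based: pool `k` derives a child seed from `(master, k)`,
so a pool is bitwise reproducible without generating its predecessors. An
optional `pdd_fraction` assigns the density-independent control kind to a
seeded subset of species, emulating analyses where only a fraction of the
community undergoes positive density dependence.

What the generator does **not** emulate: pairwise coupling between
`α_{j,i}` and `α_{i,j}` (draws are independent), phylogenetic or trait
structure, niche axes, and the exact supplementary bounds. A green
multispecies test therefore establishes that the *mechanism* (richness
maintained at high `s`, assembly failing from rarity) operates in uniform
random communities of this design — not that any particular published
richness distribution is reproduced.

# Experiments

* `richness_experiment()`: all species start at density 1 (abundant — the
  regime where positive density dependence helps), each pool is run to
  equilibrium at each `s`, and final richness plus convergence and
  local-stability flags are recorded. Every converged multi-survivor state
  is verified to sit at a locally stable equilibrium of the pruned system.
* `assembly_experiment()`: species are introduced one at a time, in a
  seeded random order, at `intro_density = 1e-2` — an order of magnitude
  above the extinction threshold; the source says only "very low density",
  so this default is a declared choice, config-exposed. Each introduction
  equilibrates before the next. Because invaders start rare, the same
  positive density dependence that preserves richness under simultaneous
  starts now suppresses it: assembly richness never exceeds the
  simultaneous-start richness of the same pool in the bundled tests.

The acceptance tests run these at reduced scale (50 pools × 30 species,
and 20 pools for the assembly comparison) to fit a single-CPU budget; the
full 500 × 100 scale is supported through the same functions and the CLI.

# Known limitations

* Deterministic only: no demographic or environmental stochasticity, hence
  nothing about the robustness of locally stable coexistence to
  perturbation (the source defers this too).
* Basin *geometry* is not computed — only the tristate attractor status via
  probe grid and invasion analysis. A `global_attractor` label is evidence
  from 25 probed initial conditions plus invasion rates, not a Lyapunov
  proof.
* The s-threshold curve is numerical; no closed form is provided.
* Classification near bifurcation boundaries is intentionally inconclusive
  within a `1e-8` eigenvalue margin.
* The supplementary alternative mortality functions are approximated by
  declared stand-ins (see the registry section).

```{r session}
sessionInfo()
```
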