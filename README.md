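# cpdd — species coexistence under positive density-dependent mortality

`cpdd` is an R package for theoretical community ecology. It asks what
happens to competing species when **conspecific positive density
dependence** acts on an **extrinsic mortality** term — i.e. when mortality
(predation, establishment failure, ...) declines with the density of
conspecifics, as in aposematic butterflies, flocking seabirds, cooperative
hunters or high-density mussel beds. Classical expectation: any positive
density dependence amplifies the advantage of the commoner species and so
promotes exclusion. The models implemented here show the opposite can hold
when the positive feedback acts on mortality: it can *create* feasible
coexistence equilibria (albeit only locally stable ones) and maintain
species-rich communities.

## The model

Densities are scaled to carrying capacity and time to the growth rate. The
core two-species system with asymmetric resource competition is

    dn1/dt = n1 [ 1 − n1 − d·D(n1) ]
    dn2/dt = n2 [ 1 − n2 − α1·n1 − d·D(n2) ]

with the hyperbolic density-dependent mortality multiplier

    D(n) = 1 / (1 + s·n),     D′(0) = −s,

where `d ∈ [0,1]` is the basal mortality rate and `s ≥ 0` the
density-dependence factor (`s = 0`: constant mortality). Two further
two-species systems replace the competitive asymmetry `α1` by a
basal-mortality difference `δ` (species 2 dies at rate `d + δ(1−d)`) or by
asymmetric **reproductive interference** `α1′`, a frequency-dependent
reduction of species 2's growth term to `1 / (1 + α1′ n1/n2)`. The
N-species generalization is

    dni/dt = ni [ 1/(Σj α′j,i nj/ni) − Σj αj,i nj − (d + δi(1−d))·D(ni) ]

with `αi,i = α′i,i = 1`.

The package provides, for these systems:

* equilibrium location (closed-form single-species roots, multi-start
  Newton for interior points), feasibility, Jacobian local stability;
* invasion growth rates of rare species at boundary attractors;
* the tristate classification of coexistence — **none** / **local
  attractor** / **global attractor** — by invasion analysis plus a basin
  probe grid;
* parameter-plane scans over (asymmetry, `s`) and numerical extraction of
  the `s` thresholds where the class changes;
* seeded random species pools (four scenarios of asymmetry) and
  deterministic multispecies simulations — simultaneous start and
  one-at-a-time assembly — with an extinction threshold of `1e-3`,
  integrated by an adaptive Dormand–Prince RK45 core written in C++.

## Worked example

```r
library(cpdd)

# Strong asymmetric competition, high basal mortality, strong positive
# density dependence: coexistence exists but cannot be assembled from rarity.
p <- two_species_params("asym_competition", d = 0.9, alpha1 = 0.5,
                        mortality = mortality_spec("hyperbolic", 50))
classify_coexistence(p)
#> <coexistence_class> local_attractor
#>   coexistence equilibrium: (0.982037, 0.472428), max Re(eig) = -0.437

# Where does the classification change along s at d = 0.9, alpha1 = 0.5?
find_s_threshold("asym_competition", list(d = 0.9), x_value = 0.5)
#>          s             from              to
#> 1 0.625098 global_attractor            none
#> 2 7.524135             none local_attractor

# Multispecies: random pools differing in basal mortality (scenario 3)
cfg <- pool_config("basal_mortality_only", n_species = 30, seed = 1)
df <- richness_experiment(cfg, n_pools = 5, s_values = c(0, 10, 1e4))
aggregate(final_richness ~ s, df, mean)
#>       s final_richness
#> 1     0           20.2
#> 2    10           27.2
#> 3 10000           30.0
```

Reading: at low `s` coexistence is a global attractor; over `s ≈ 0.63–7.5`
(for `d = 0.9`, `α1 = 0.5`) the coexistence equilibrium disappears; above,
it reappears as a local attractor whose weaker-species density grows with
`s`. In the 30-species pools, mean surviving richness is lowest without
positive density dependence (20.2 of 30 species), and extreme
density-dependence factors preserve the full pool (30.0) — positive density
dependence acting on mortality maintains species-rich communities when all
species start abundant.

## Command line

```sh
inst/cli/cpdd classify --model asym_competition --d 0.9 --alpha1 0.5 --s 0.01
inst/cli/cpdd scan --config run.yaml --out-dir results
```

Commands: `classify`, `scan`, `threshold`, `richness`, `assembly`. Each run
writes a CSV of records plus a JSON sidecar echoing the fully resolved
configuration (YAML schema documented in `?read_config`).

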