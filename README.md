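# serialdil — serial-dilution consumer-resource ecosystems

`serialdil` simulates and analyzes microbial communities competing for
substitutable nutrients in **serial batch culture**: each batch starts
with a nutrient bolus and a fixed inoculum, the community grows until the
nutrients are gone, and a sample seeds the next batch. It is aimed at
theoretical ecologists and microbiologists studying how *metabolic
trade-offs* shape community diversity when nutrients arrive in seasonal
pulses rather than continuously (as in a chemostat).

## The model

A species σ is an **enzyme-allocation strategy**
α⃗<sub>σ</sub> = (α<sub>σ,1</sub>, …, α<sub>σ,p</sub>) on the nutrient
simplex, constrained by a shared enzyme budget
∑<sub>i</sub> α<sub>σ,i</sub> = E + ε ξ<sub>σ</sub> (ξ<sub>σ</sub>
standard normal; ε = 0 gives exact trade-offs). Within a batch, uptake
follows Monod kinetics:

- uptake: j<sub>σ,i</sub> = α<sub>σ,i</sub> c<sub>i</sub>/(K<sub>i</sub> + c<sub>i</sub>)
- nutrients: dc<sub>i</sub>/dt = −∑<sub>σ</sub> ρ<sub>σ</sub> (j<sub>σ,i</sub> − ∑<sub>i′</sub> Γ<sub>i,i′</sub> j<sub>σ,i′</sub>)
- biomass: dρ<sub>σ</sub>/dt = ρ<sub>σ</sub> ∑<sub>i</sub> Y<sub>i</sub> j<sub>σ,i</sub>

with yields Y<sub>i</sub> (unit by default) and an optional byproduct
matrix Γ (cross-feeding: consuming nutrient i′ secretes nutrient i).
The per-nutrient **Monod integrals** I<sub>i</sub> = ∫ c<sub>i</sub>/(K<sub>i</sub>+c<sub>i</sub>) dt
summarize a batch: every species' fold increase is
exp(∑<sub>i</sub> α<sub>σ,i</sub> Y<sub>i</sub> I<sub>i</sub>), so
arbitrary coexistence requires equal yield-weighted Monod integrals.
Batches are chained by dilution back to inoculum density ρ<sub>0</sub>
(deterministically, or by sampling a finite number of cells with an
optional migrant spike-in) until the composition stops changing.

On top of the simulator the package provides the analytical machinery:

- the chemostat-limit (c<sub>0</sub> ≪ K) steady-state balance and its
  per-species residuals,
- **remapped coexistence boundaries** — the supply composition at which
  all nutrients are equally valuable over a resident's batch, which
  shifts with bolus size c<sub>0</sub> and drives the "early-bird"
  loss/recovery of coexistence,
- the **convex-hull criterion** (supply inside the hull of strategies ⇒
  unlimited coexistence in the chemostat limit), invasion folds, and
  mutual-invasibility windows,
- Shannon diversity / effective number of species m<sub>e</sub> = e^S,
  and parameter sweeps of m<sub>e</sub> against bolus size for the
  baseline, unequal-K, unequal-Y, cross-feeding, stochastic-bottleneck
  and alternating-bolus variants.

## Worked example

Twenty-one equally spaced strategies compete for two nutrients supplied
95:5 at bolus size c<sub>0</sub> = K:

```r
library(serialdil)
s   <- equally_spaced_strategies(21)
env <- nutrient_env(c0 = 1, supply_fraction = c(0.05, 0.95),
                    K = 1, rho0 = 1e-3)
run_to_steady_state(rep(1, 21), s, env,
                    control = protocol_control(max_batches = 8000,
                                               steady_state_tol = 1e-8))
#> Serial-dilution steady state (converged)
#>   batches used: 63  contraction factor: 0.7415
#>   survivors: 13 of 21
#>   effective species m_e = 1.70124
```

The skewed supply plus the early-bird effect collapse the effective
diversity to m<sub>e</sub> ≈ 1.7 (out of a possible 21): species feeding
on the abundant nutrient outgrow the rest early in each batch and then
strip the scarce nutrient too. The same community under a balanced
(0.5, 0.5) supply keeps m<sub>e</sub> = 21 at every bolus size. The
remapping that causes this is visible directly:

```r
remapped_boundary(c(0.2, 0.8), env)
#> Remapped coexistence boundary
#>   strategy: 0.2, 0.8
#>   boundary: 0.384466, 0.615534
#>   residual: 1.06e-10
```

At c<sub>0</sub> = K the strategy (0.2, 0.8) only coexists neutrally
with invaders if the supply sits at (0.384, 0.616) — far from the
strategy itself. In both the c<sub>0</sub> → 0 and c<sub>0</sub> → ∞
limits the boundary returns to (0.2, 0.8).

A command-line front end for config-driven runs is installed at
`system.file("cli/ecosim.R", package = "serialdil")` with subcommands
`serial`, `stochastic`, `remap`, `hull`, `diversity`, `sweep`.

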