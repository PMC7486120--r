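---
title: "Methods: the serial-dilution consumer-resource model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the serial-dilution consumer-resource model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(serialdil)
```

## The model and its assumptions

`serialdil` models a community of species competing for $p$
substitutable nutrients in repeated batch culture. A species $\sigma$
is its enzyme-allocation strategy $\vec\alpha_\sigma$, a point on the
nutrient simplex: $\alpha_{\sigma,i} \ge 0$ is the share of the
species' enzyme budget devoted to nutrient $i$, with
$\sum_i \alpha_{\sigma,i} = E + \varepsilon\,\xi_\sigma$ and
$\xi_\sigma \sim \mathcal N(0,1)$. The budget constraint is the
metabolic trade-off: a cell's biosynthetic capacity is finite, so
investing in one transporter comes at the expense of another. With
exact trade-offs ($\varepsilon = 0$) the budget is an equalizing
mechanism — no species is intrinsically superior — and arbitrarily many
species can coexist under the right supply.

Within a batch, per-biomass uptake follows Monod kinetics,
$j_{\sigma,i} = \alpha_{\sigma,i}\, c_i/(K_i + c_i)$, and the coupled
dynamics are

$$\frac{dc_i}{dt} = -\sum_\sigma \rho_\sigma\Big(j_{\sigma,i}
  - \sum_{i'} \Gamma_{i,i'}\, j_{\sigma,i'}\Big), \qquad
  \frac{d\rho_\sigma}{dt} = \rho_\sigma \sum_i Y_i\, j_{\sigma,i},$$

where $\Gamma_{i,i'}$ converts consumption of nutrient $i'$ into
secretion of nutrient $i$ (cross-feeding, zero by default) and $Y_i$ is
the biomass yield per unit of nutrient $i$ (unit by default, recovering
the conservative form in which final total biomass is exactly
$\rho_0 + c_0$). Assumptions worth keeping in mind: all nutrients are
substitutable and consumed simultaneously; there are no lag phases,
death, maintenance costs, or within-batch nutrient inflow; byproduct
secretion is tied stoichiometrically to consumption at no enzymatic
cost.

A batch ends when the nutrients are depleted; the next batch is seeded
at total density $\rho_0$ with the final composition. The object that
controls everything across a batch is the vector of Monod integrals
$I_i = \int_0^{t_f} c_i/(K_i + c_i)\,dt$: species $\sigma$ grows by the
factor $\exp(\sum_i \alpha_{\sigma,i} Y_i I_i)$. Coexistence of
arbitrarily many strategies therefore requires all the $Y_i I_i$ to be
equal, and the supply compositions for which a resident produces equal
$Y_i I_i$ — its *remapped coexistence boundary* — organize the entire
phenomenology: boundaries coincide with the strategies in both the
$c_0 \ll K$ (chemostat) and $c_0 \gg K$ (saturated) limits and are
pulled toward the simplex center in between, maximally near
$c_0 \approx K$, which is how bolus size reshapes diversity.

## Tunable parameters

All concentrations share one (arbitrary) concentration unit; time is
fixed by the maximal uptake rate (budget $E = 1$ per unit time).

| parameter | meaning | default | notes |
|---|---|---|---|
| `c0` | total bolus concentration | — | the key control variable; scan it in units of $K$ |
| `supply_fraction` | bolus composition $c_i(0)/c_0$ | — | a simplex point |
| `K` | Monod half-saturation constants | 1 | `c0/K` sets the regime: $\ll 1$ chemostat-like, $\gg 1$ saturated |
| `Y` | biomass per unit nutrient | 1 | unit yields make total biomass conservative |
| `rho0` | inoculum biomass density | — | canonical study value $\rho_0/K = 10^{-3}$; remapping requires $\rho_0 \ll K$ |
| `budget`, `epsilon` | enzyme budget and its spread | 1, 0 | $\varepsilon = 0.1$ gives the 10%-budget-spread variant |
| `byproduct` | conversion matrix $\Gamma$ | 0 | `byproduct_matrix(g)` builds the 2-nutrient bitrophic case |

Protocol-level knobs (`protocol_control()`): `steady_state_tol`
(default `1e-10`) with `sustain = 3` consecutive sub-tolerance batches;
`decline_tol = 1e-6` and `decline_batches = 10` defining sustained
geometric decline; `max_batches` (default `1e5`) as the
critical-slowing-down escape hatch — near a coexistence transition the
number of batches to steady state diverges, and such runs return
`converged = FALSE` together with the measured per-batch contraction
factor rather than iterating forever.

## What the configuration generators emulate — and what they do not

`equally_spaced_strategies(m)` builds the canonical community: $m$
strategies evenly spaced on the two-nutrient simplex (for $p > 2$, a
regular lattice with $m$ points per edge — the spacing convention for
higher dimensions is ours, as no standard exists), with exact unit
budgets. `sample_budget_noise()` relaxes the trade-off
multiplicatively, preserving allocation fractions; non-positive budget
draws are rejected and redrawn (vanishingly rare at $\varepsilon =
0.1$, but the count is recorded). `fixture_configs()` packages the
canonical study conditions: $\rho_0/K = 10^{-3}$ with six supply
compositions (first-nutrient fractions 0.05–0.5; beyond 0.5 by the
model's mirror symmetry), $K = (10^{-3}, 1)$ and $Y = (10, 1)$ variants
at $\rho_0 = 1$, the bitrophic chain with only Nutrient 2 supplied, and
the 1008-cell bottleneck with a 50-cell spike-in from 21 equally
abundant strategies.

These configurations are idealizations. Real communities do not have
evenly spaced strategies, identical budgets, or a fixed global migrant
pool; real nutrients are often complementary rather than substitutable;
and real growth includes lags and death. Tests passing on these
configurations validate the model's internal logic (conservation laws,
the fold identity, the hull rule, remapping limits) — they do not by
themselves certify that any particular natural community behaves this
way.

## Numerical choices

* **Integrator.** Each batch is one `deSolve::lsodar` solve (adaptive,
  stiffness-switching) with the right-hand side compiled in C. Default
  tolerances `rtol = 1e-10` and `atol = 1e-14` on concentration states;
  biomass states use `atol = 0` (biomass is strictly positive and
  multiplicative, so relative control is the correct scale even for an
  invader at $10^{-9}\rho_0$). Species with zero inoculum are removed
  before the solve and reinserted after.
* **Quadratures.** The Monod integrals and the consumption/production
  ledgers are extra quadrature states of the same solve — never
  post-hoc trapezoids on sampled output — so they inherit the
  integrator's error control. The fold-increase identity
  $\rho_\sigma(t_f)/\rho_\sigma(0) = \exp(\sum_i \alpha_{\sigma,i} Y_i
  I_i)$ is exact for the continuous system and serves as the suite's
  primary integration-accuracy oracle (relative tolerance $10^{-6}$).
* **Depletion event.** Exact depletion takes infinite time (the tail is
  exponential), so a batch terminates when total remaining *consumable*
  nutrient falls below `depletion_fraction` (default $10^{-9}$) of the
  total eventually-consumable supply, located by `lsodar`'s root-finder
  rather than step truncation. Nutrients no present species can consume
  are excluded from the event (they would make depletion unreachable);
  with byproducts, the eventually-consumable total solves
  $C = c(0) + \Gamma C$, which requires the spectral radius of
  $\Gamma$ below 1. Tightening the threshold to $10^{-12}$ moves the
  Monod integrals by less than $10^{-6}$ relative.
* **Steady-state detection.** Convergence is the maximum per-species
  relative change of the inoculum composition across one batch (one
  supply cycle, for periodic schedules), sustained for three batches.
  Species in *sustained geometric decline* — fold below
  $1 - 10^{-6}$ for ten consecutive batches — are excluded from the
  criterion (a dying species' relative change never vanishes) and from
  the survivor set; survivors must additionally exceed a $10^{-10}$
  relative-abundance floor. At large $c_0$ a single batch spans many
  e-folds of growth and amplifies integration error into a composition
  noise floor around $10^{-9}$; sweeps in that regime therefore use
  `steady_state_tol = 1e-8`, still orders of magnitude below any
  quantity asserted on.
* **Remapped boundaries.** For $p = 2$, bracketed root-finding
  (`uniroot`, composition tolerance $10^{-10}$, brackets
  $[10^{-12}, 1 - 10^{-12}]$) on the monotone difference
  $Y_1 I_1 - Y_2 I_2$ of a single resident batch at inoculum $\rho_0$
  (a monoculture reaches its serial-dilution steady state in one
  batch). If the difference does not change sign the boundary is
  reported at the corresponding vertex. Nutrients outside the
  strategy's support are pinned to zero supply: the resident never
  consumes them, their Monod integral diverges with the depletion
  threshold, and the exact equal-value limit therefore sits on the
  support face — this is what makes specialists exactly unremapped
  rather than spuriously shifted by the finite threshold. For
  $p \ge 3$ a Nelder–Mead search on a softmax chart of the support
  simplex minimizes the spread of the $Y_i I_i$.
* **Equal value under unequal yields.** The boundary condition is
  stated as equal *yield-weighted* integrals $Y_i I_i$. This reduces to
  equal $I_i$ for unit yields and makes the invader fold
  $\exp(\sum_i \alpha_i Y_i I_i)$ strategy-independent exactly at the
  boundary, which is the defining property a coexistence boundary must
  have; it reproduces the unremapped limits at both small and large
  $c_0$.
* **Yield convention.** Yields multiply growth
  ($\dot\rho_\sigma = \rho_\sigma \sum_i Y_i j_{\sigma,i}$) while
  consumption stays in concentration units, so $Y_i$ is biomass per
  unit nutrient and total biomass obeys
  $\sum_\sigma \rho_\sigma(t_f) = \rho_0 + \sum_i Y_i c_i(0)$. Supply
  compositions for the unequal-yield variant are optionally
  *yield-normalized* (composition $\phi$ becomes supply fraction
  $(\phi/Y_1)/(\phi/Y_1 + (1-\phi)/Y_2)$) so that the nominal
  composition measures biomass potential rather than concentration.
  Under this convention the mirror symmetry between compositions is
  broken at saturating bolus sizes and the two members of a mirrored
  pair diverge — one gaining, one losing diversity — with the
  yield-balanced composition declining monotonically.
* **Bottleneck integerization.** Final biomass is converted to cells at
  the quantum $\rho_0/n_{\text{cells}}$ with stochastic rounding of
  fractional cells; the resident draw is multivariate hypergeometric
  (sequential conditional `rhyper`), and the spike-in is multinomial
  over the pool (50 cells over 21 species cannot be equal, so equal
  *probabilities* are redrawn each dilution). For populations above
  $2^{30}$ cells the without-replacement correction is
  $O(n_{\text{cells}}/N) < 10^{-6}$ and the draw is taken
  multinomially. All randomness flows through one seeded generator per
  run; the ambient RNG state is always restored.
* **Convex hull.** Membership is linear feasibility — non-negative
  weights reproducing the supply, found by a hand-written
  Lawson–Hanson non-negative least squares (the problems are tiny);
  since points and supply are simplex compositions, feasible weights
  sum to 1 automatically. Boundary points count as contained; the
  signed margin is exact for two nutrients and Euclidean on the ternary
  embedding for three.

## Problem sizes used by the test suite

The suite runs the canonical 21-strategy community wherever a check is
about the study conditions themselves (maximal diversity, chemostat
correspondence, U-shaped diversity, bottleneck statistics) and smaller
communities (4–11 strategies) for property checks where the property is
size-independent (hull-rule verdicts, window verdicts, trend
reversals), keeping the whole suite within a few minutes: diversity
sweeps use 3-point $c_0$ grids at the regime extremes plus $c_0 = K$,
steady-state runs are capped at 4000–60 000 batches depending on the
regime's contraction rate, and the chemostat-balance check runs at
$c_0 \ll \rho_0 \ll K$ ($\rho_0/K = 0.1$, $c_0/K = 10^{-4}$) where the
first-order balance is valid — at $\rho_0/K = 10^{-3}$ the finite
$c_0/\rho_0 = 0.1$ correction ($\ln(1+c_0/\rho_0)$ versus $c_0/\rho_0$)
dominates the residual, which is a property of the expansion, not of
the simulation.

## Known limitations

* Near a coexistence transition, convergence stalls (critical slowing
  down); results there carry `converged = FALSE` and a contraction
  factor, and the survivor classification — not full convergence — is
  the reliable readout. Slowly declining species that have not yet
  crossed the decline detector can inflate the survivor count in a
  finite run.
* The chemostat-limit balance and its residuals assume exact trade-offs
  and first order in $c_0/K$ *and* $c_0/\rho_0$; they are diagnostics
  for the small-bolus regime only.
* The remapping search for $p \ge 3$ is a local optimization without
  the $p = 2$ uniqueness guarantee, and the coexistence region for
  $p \ge 3$ is approximated by the hull of remapped boundary points.
* Byproduct matrices with spectral radius $\ge 1$ (lossless nutrient
  cycles) are rejected rather than simulated.
* No evolutionary dynamics, no complementary (co-limiting) nutrients,
  no species-specific yields.
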