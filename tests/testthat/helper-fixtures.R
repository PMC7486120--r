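# Shared fixtures: everything is generated in code, nothing read from disk.

env2n <- function(c0 = 1, supply = c(0.5, 0.5), K = 1, Y = 1,
                  rho0 = 1e-3, byproduct = NULL) {
  nutrient_env(c0 = c0, supply_fraction = supply, K = K, Y = Y,
               byproduct = byproduct, rho0 = rho0)
}

# Random two-nutrient community with well-separated strategies inside
# [lo, hi], so that hull membership of a supply has a clear margin.
random_two_nutrient_community <- function(m, lo = 0.15, hi = 0.85,
                                          min_gap = 0.03) {
  a1 <- sort(runif(m, lo, hi))
  while (min(diff(a1)) < min_gap) a1 <- sort(runif(m, lo, hi))
  strategy_set(cbind(a1, 1 - a1))
}

# Random strategy matrix with unit budgets and full support.
random_strategy_rows <- function(m, p) {
  a <- matrix(runif(m * p, 0.05, 1), m, p)
  a / rowSums(a)
}
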