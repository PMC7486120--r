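#' Nutrient environment of a serial-dilution batch
#'
#' Describes the bolus supplied at the start of each batch and the uptake
#' parameters: total bolus concentration `c0`, supply composition (the
#' fractions \eqn{c_i(0)/c_0} on the nutrient simplex), Monod constants
#' `K`, biomass yields `Y` (biomass produced per unit nutrient consumed),
#' an optional byproduct matrix for cross-feeding, and the inoculum
#' biomass density `rho0` at which every batch starts.
#'
#' The byproduct matrix \eqn{\Gamma} converts consumption of nutrient
#' \eqn{i'} into production of nutrient \eqn{i} (entry `byproduct[i, i']`)
#' at no extra enzymatic cost; a zero matrix means a single trophic layer.
#' For the canonical two-nutrient case where Nutrient 1 arises solely as a
#' byproduct of consuming Nutrient 2, use [byproduct_matrix()].
#'
#' @param c0 total bolus concentration (> 0).
#' @param supply_fraction non-negative fractions summing to 1; its length
#'   sets the number of nutrients `p`.
#' @param K Monod half-saturation constants, recycled to length `p`.
#' @param Y nutrient-to-biomass yields, recycled to length `p` (default 1,
#'   i.e. ideal conversion).
#' @param byproduct `p x p` non-negative matrix with zero diagonal, or
#'   `NULL` for no cross-feeding.
#' @param rho0 total inoculum biomass density (> 0).
#' @return An object of class `nutrient_env`.
#' @examples
#' env <- nutrient_env(c0 = 1, supply_fraction = c(0.5, 0.5),
#'                     K = 1, rho0 = 1e-3)
#' @export
nutrient_env <- function(c0, supply_fraction, K = 1, Y = 1,
                         byproduct = NULL, rho0) {
  if (!is.numeric(c0) || length(c0) != 1L || c0 <= 0)
    stop_invalid("c0 must be a single positive number")
  if (!is.numeric(rho0) || length(rho0) != 1L || rho0 <= 0)
    stop_invalid("rho0 must be a single positive number")
  supply_fraction <- as.numeric(supply_fraction)
  p <- length(supply_fraction)
  if (p < 1L) stop_invalid("supply_fraction must be non-empty")
  if (any(supply_fraction < 0))
    stop_invalid("supply_fraction entries must be >= 0")
  if (abs(sum(supply_fraction) - 1) > 1e-12)
    stop_invalid("supply_fraction must sum to 1 (within 1e-12)")
  K <- rep_len(as.numeric(K), p)
  Y <- rep_len(as.numeric(Y), p)
  if (any(K <= 0) || any(Y <= 0))
    stop_invalid("K and Y must be strictly positive")
  if (is.null(byproduct)) byproduct <- matrix(0, p, p)
  byproduct <- as.matrix(byproduct)
  if (!all(dim(byproduct) == c(p, p)))
    stop_invalid("byproduct must be a ", p, " x ", p, " matrix")
  if (any(byproduct < 0) || any(diag(byproduct) != 0))
    stop_invalid("byproduct entries must be >= 0 with a zero diagonal")
  if (p > 64L)
    stop_invalid("at most 64 nutrients are supported")

  structure(list(p = p, c0 = c0, supply_fraction = supply_fraction,
                 K = K, Y = Y, byproduct = unname(byproduct), rho0 = rho0),
            class = "nutrient_env")
}

#' Two-nutrient byproduct matrix
#'
#' Builds the matrix `rbind(c(0, gamma), c(0, 0))`: consumption of
#' Nutrient 2 produces Nutrient 1 at conversion fraction `gamma`.
#'
#' @param gamma non-negative conversion fraction.
#' @return A 2 x 2 byproduct matrix.
#' @export
byproduct_matrix <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop_invalid("gamma must be a single non-negative number")
  matrix(c(0, 0, gamma, 0), 2L, 2L)
}

#' @export
print.nutrient_env <- function(x, ...) {
  cat("Nutrient environment:", x$p, "nutrients\n")
  cat("  c0 =", x$c0, " rho0 =", x$rho0, "\n")
  cat("  supply fractions:", paste(signif(x$supply_fraction, 4),
                                   collapse = ", "), "\n")
  cat("  K:", paste(signif(x$K, 4), collapse = ", "),
      "  Y:", paste(signif(x$Y, 4), collapse = ", "), "\n")
  if (any(x$byproduct > 0)) cat("  cross-feeding byproduct matrix present\n")
  invisible(x)
}

#' Instantaneous community state
#'
#' Bundles biomass densities, nutrient concentrations and time; the uptake
#' matrix is derived on demand by [uptake_rates()].
#'
#' @param rho non-negative biomass densities.
#' @param c non-negative nutrient concentrations.
#' @param t non-negative time (default 0).
#' @return An object of class `community_state`.
#' @export
community_state <- function(rho, c, t = 0) {
  rho <- as.numeric(rho); c <- as.numeric(c)
  if (any(!is.finite(rho)) || any(rho < 0))
    stop_invalid("rho must be finite and non-negative")
  if (any(!is.finite(c)) || any(c < 0))
    stop_invalid("negative or non-finite concentrations are not a valid state")
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop_invalid("t must be a single non-negative number")
  structure(list(rho = rho, c = c, t = t), class = "community_state")
}

#' Per-capita nutrient uptake rates
#'
#' Evaluates the Monod uptake law
#' \deqn{j_{\sigma,i} = \alpha_{\sigma,i} \frac{c_i}{K_i + c_i},}
#' the rate (per unit biomass) at which species \eqn{\sigma} consumes
#' nutrient \eqn{i}.  Entries are bounded by the allocations:
#' \eqn{0 \le j \le \alpha}.
#'
#' @param state a [community_state()] (its `c` component is used).
#' @param strategies a [strategy_set()].
#' @param env a [nutrient_env()].
#' @return Matrix of uptake rates, species x nutrients.
#' @export
uptake_rates <- function(state, strategies, env) {
  if (!inherits(state, "community_state"))
    stop_invalid("state must be a community_state")
  validate_strategy_set(strategies)
  p <- ncol(strategies$alpha)
  if (length(state$c) != p || env$p != p)
    stop_invalid("dimension mismatch between state, strategies and env")
  monod <- state$c / (env$K + state$c)
  sweep(strategies$alpha, 2L, monod, `*`)
}

#' Write a community configuration to JSON
#'
#' Serializes a strategy set and a nutrient environment to a JSON config
#' that [read_config()] restores loss-free at full float precision.
#'
#' @param strategies a `strategy_set`.
#' @param env a `nutrient_env`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_config <- function(strategies, env, path) {
  validate_strategy_set(strategies)
  cfg <- list(
    strategies = list(
      labels = strategies$labels,
      alpha = apply(strategies$alpha, 1L, identity, simplify = FALSE),
      budget = strategies$budget,
      epsilon = strategies$epsilon,
      xi = strategies$xi),
    environment = list(
      p = env$p, c0 = env$c0, supply_fraction = env$supply_fraction,
      K = env$K, Y = env$Y,
      byproduct = apply(env$byproduct, 1L, identity, simplify = FALSE),
      rho0 = env$rho0))
  # digits = I(17): significant digits, enough for exact double round-trip
  jsonlite::write_json(cfg, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a community configuration from JSON
#'
#' @param path file written by [write_config()].
#' @return A list with elements `strategies` and `env`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- cfg$strategies
  alpha <- if (is.list(s$alpha)) do.call(rbind, s$alpha) else as.matrix(s$alpha)
  if (ncol(alpha) == 1L && cfg$environment$p > 1L) alpha <- t(alpha)
  e <- cfg$environment
  byp <- if (is.list(e$byproduct)) do.call(rbind, e$byproduct)
         else as.matrix(e$byproduct)
  list(
    strategies = strategy_set(alpha, budget = s$budget, epsilon = s$epsilon,
                              xi = s$xi, labels = s$labels),
    env = nutrient_env(c0 = e$c0, supply_fraction = e$supply_fraction,
                       K = e$K, Y = e$Y, byproduct = byp, rho0 = e$rho0))
}
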