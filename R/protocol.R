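#' Dilute a finished batch into the next inoculum
#'
#' The next batch is seeded at total density `rho0` with the composition
#' of the final biomass: `inoculum = rho0 * rho_final / sum(rho_final)`.
#' At steady state the final densities are `(rho0 + c0)/rho0` times the
#' inoculum, so diluting returns the same inoculum.
#'
#' @param batch a `batch_result`.
#' @param rho0 total inoculum density for the next batch.
#' @return Numeric inoculum vector summing to `rho0`.
#' @export
dilute <- function(batch, rho0 = batch$env$rho0) {
  if (!inherits(batch, "batch_result"))
    stop_invalid("batch must be a batch_result")
  tot <- sum(batch$rho_final)
  if (!is.finite(tot) || tot <= 0)
    stop_invalid("zero total biomass: cannot dilute")
  rho0 * batch$rho_final / tot
}

#' Protocol options for serial dilution to steady state
#'
#' @param max_batches cap on the number of batches (default 1e5); runs
#'   near a coexistence transition exhibit critical slowing down and are
#'   reported with `converged = FALSE` plus the measured contraction
#'   factor instead of running forever.
#' @param steady_state_tol maximum per-species relative change of the
#'   inoculum composition per batch at steady state (default 1e-10),
#'   required for `sustain` consecutive batches.
#' @param sustain consecutive sub-tolerance batches required (default 3).
#' @param decline_tol a species whose relative abundance shrinks by a
#'   factor below `1 - decline_tol` per batch is declining (default 1e-6).
#' @param decline_batches consecutive declining batches after which a
#'   species counts as being in sustained geometric decline (default 10);
#'   such species are excluded from the convergence criterion (their
#'   relative change never vanishes) and from the survivor set.
#' @param extinction_floor relative abundance below which a species is
#'   never a survivor (default 1e-10).
#' @param batch a [batch_control()] used for every batch.
#' @param keep_history record the per-batch inoculum compositions?
#' @return A list of class `protocol_control`.
#' @export
protocol_control <- function(max_batches = 1e5, steady_state_tol = 1e-10,
                             sustain = 3L, decline_tol = 1e-6,
                             decline_batches = 10L,
                             extinction_floor = 1e-10,
                             batch = batch_control(),
                             keep_history = FALSE) {
  structure(list(max_batches = as.integer(max_batches),
                 steady_state_tol = steady_state_tol,
                 sustain = as.integer(sustain),
                 decline_tol = decline_tol,
                 decline_batches = as.integer(decline_batches),
                 extinction_floor = extinction_floor,
                 batch = batch, keep_history = keep_history),
            class = "protocol_control")
}

#' Serial dilution to steady state
#'
#' Chains [run_batch()] and [dilute()] until the inoculum composition
#' stops changing: the maximum per-species relative change over a batch
#' must stay below `steady_state_tol` for `sustain` consecutive batches.
#' Species in sustained geometric decline (headed for extinction) are
#' excluded from the convergence test and flagged as non-survivors.
#'
#' With a periodic supply schedule (see [bolus_schedule()]) compositions
#' are compared one full cycle apart and "steady state" means a stable
#' limit cycle.
#'
#' @param inoculum0 initial densities (rescaled to total `env$rho0`).
#' @param strategies a [strategy_set()].
#' @param env a [nutrient_env()].
#' @param control a [protocol_control()].
#' @param schedule optional [bolus_schedule()]; `NULL` means the constant
#'   mixed bolus in `env`.
#' @return An object of class `steady_state_result`: `rho_star`
#'   (steady-state inoculum abundances, summing to `rho0`),
#'   `batches_used`, `converged`, `convergence_rate` (estimated per-batch
#'   geometric contraction of the composition change), `survivors`
#'   (logical), `diversity` (an [effective_species()] summary),
#'   `last_batch`, and `history` when requested.
#' @examples
#' env <- nutrient_env(c0 = 1e-3, supply_fraction = c(0.5, 0.5),
#'                     K = 1, rho0 = 1e-3)
#' s <- equally_spaced_strategies(5)
#' run_to_steady_state(rep(1, 5), s, env)
#' @export
run_to_steady_state <- function(inoculum0, strategies, env,
                                control = protocol_control(),
                                schedule = NULL) {
  validate_strategy_set(strategies)
  m <- nrow(strategies$alpha)
  inoculum0 <- as.numeric(inoculum0)
  if (length(inoculum0) != m || any(inoculum0 < 0) || sum(inoculum0) <= 0)
    stop_invalid("inoculum0 must be non-negative with positive sum")
  period <- if (is.null(schedule)) 1L else schedule$period
  nhist <- control$decline_batches

  rho0 <- env$rho0
  f <- inoculum0 / sum(inoculum0)
  # ring buffers: compositions one period apart, per-species fold history
  f_ref <- matrix(rep(f, period), nrow = m)   # compositions, lag 1..period
  folds <- matrix(NA_real_, m, nhist)
  history <- if (control$keep_history)
    matrix(NA_real_, control$max_batches, m) else NULL

  converged <- FALSE
  stable <- 0L
  deltas <- rep(NA_real_, 6L)
  batches <- 0L
  last_batch <- NULL

  for (b in seq_len(control$max_batches)) {
    env_b <- env
    if (!is.null(schedule)) env_b$supply_fraction <- schedule$supply(b)
    last_batch <- tryCatch(
      run_batch(rho0 * f, strategies, env_b, control$batch),
      error = function(e) stop("batch ", b, ": ", conditionMessage(e),
                               call. = FALSE))
    f_new <- dilute(last_batch, rho0) / rho0
    batches <- b
    if (!is.null(history)) history[b, ] <- f_new

    slot <- ((b - 1L) %% period) + 1L
    f_old <- f_ref[, slot]
    f_ref[, slot] <- f_new

    fold <- ifelse(f_old > 0, f_new / f_old, ifelse(f_new > 0, Inf, 1))
    folds <- cbind(folds[, -1L, drop = FALSE], fold)
    declining <- apply(folds, 1L, function(z)
      all(!is.na(z)) && all(z < 1 - control$decline_tol))

    rel <- abs(f_new - f_old) / pmax(f_old, 1e-300)
    delta <- if (all(declining)) 0 else max(rel[!declining])
    deltas <- c(deltas[-1L], delta)

    if (b >= period) {
      if (delta == 0) { converged <- TRUE; f <- f_new; break }
      stable <- if (delta < control$steady_state_tol) stable + 1L else 0L
      if (stable >= control$sustain) { converged <- TRUE; f <- f_new; break }
    }
    f <- f_new
  }

  ratios <- deltas[-1L] / deltas[-length(deltas)]
  ratios <- ratios[is.finite(ratios) & ratios > 0]
  convergence_rate <- if (length(ratios)) exp(mean(log(ratios))) else NA_real_

  declining <- apply(folds, 1L, function(z)
    all(!is.na(z)) && all(z < 1 - control$decline_tol))
  survivors <- f > control$extinction_floor & !declining

  rho_star <- rho0 * f
  structure(list(rho_star = rho_star, batches_used = batches,
                 converged = converged,
                 convergence_rate = convergence_rate,
                 survivors = survivors,
                 diversity = effective_species(rho_star, rho0),
                 labels = strategies$labels,
                 last_batch = last_batch,
                 history = if (is.null(history)) NULL else
                   history[seq_len(batches), , drop = FALSE]),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat("Serial-dilution steady state",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  batches used:", x$batches_used,
      " contraction factor:", signif(x$convergence_rate, 4), "\n")
  cat("  survivors:", sum(x$survivors), "of", length(x$survivors), "\n")
  cat("  effective species m_e =", signif(x$diversity$m_e, 6), "\n")
  invisible(x)
}

#' Bottleneck sampling configuration
#'
#' Describes the finite-cell dilution used by [bottleneck_sample()] and
#' [run_stochastic()]: each new batch is inoculated with `n_cells` cells,
#' of which `n_cells - n_spikein` are sampled without replacement from the
#' previous batch and `n_spikein` are migrants drawn from a fixed global
#' pool with composition `pool_fractions` (island-biogeography-style
#' spike-in preventing extinctions by sampling noise).
#'
#' @param n_cells total cells per inoculum.
#' @param n_spikein migrant cells per dilution (0 <= n_spikein <= n_cells).
#' @param pool_fractions pool composition over the species of the
#'   community; must sum to 1 when `n_spikein > 0`.
#' @param seed integer seed making [run_stochastic()] reproducible.
#' @return A list of class `bottleneck_config`.
#' @export
bottleneck_config <- function(n_cells, n_spikein = 0L,
                              pool_fractions = NULL, seed = 1L) {
  n_cells <- as.integer(n_cells); n_spikein <- as.integer(n_spikein)
  if (n_cells < 1L) stop_invalid("n_cells must be >= 1")
  if (n_spikein < 0L || n_spikein > n_cells)
    stop_invalid("need 0 <= n_spikein <= n_cells")
  if (n_spikein > 0L) {
    if (is.null(pool_fractions))
      stop_invalid("pool_fractions required when n_spikein > 0")
    pool_fractions <- as.numeric(pool_fractions)
    if (any(pool_fractions < 0) || abs(sum(pool_fractions) - 1) > 1e-9)
      stop_invalid("pool_fractions must be non-negative and sum to 1")
  }
  structure(list(n_cells = n_cells, n_spikein = n_spikein,
                 pool_fractions = pool_fractions, seed = as.integer(seed)),
            class = "bottleneck_config")
}

# Multivariate hypergeometric draw of k cells from integer counts.
# For very large populations (total > 2^30) the sampling fraction is
# negligible and the draw is taken multinomially (without-replacement
# corrections are O(k/total)).
rmvhyper1 <- function(counts, k) {
  m <- length(counts)
  total <- sum(counts)
  if (total > 2^30) {
    return(as.integer(rmultinom(1L, k, counts / total)[, 1L]))
  }
  out <- integer(m)
  remaining <- total
  for (s in seq_len(m)) {
    remaining <- remaining - counts[s]
    if (k <= 0L) break
    x <- rhyper(1L, counts[s], remaining, k)
    out[s] <- x
    k <- k - x
  }
  out
}

#' Sample a finite-cell bottleneck from a finished batch
#'
#' Converts the final biomass to integer cells using the cell mass quantum
#' `rho0 / n_cells` (fractional cells resolved by stochastic rounding),
#' draws `n_cells - n_spikein` resident cells without replacement
#' (multivariate hypergeometric) and adds `n_spikein` migrant cells drawn
#' multinomially from the pool.  Returned counts always sum to `n_cells`.
#'
#' @param batch a `batch_result`.
#' @param config a [bottleneck_config()].
#' @param env the environment (defaults to the one stored in `batch`);
#'   provides `rho0`.
#' @param seed optional seed; `NULL` (the default) uses the ambient RNG
#'   stream, which is how [run_stochastic()] drives it.
#' @return Integer vector of cell counts per species.
#' @export
bottleneck_sample <- function(batch, config, env = batch$env, seed = NULL) {
  if (!inherits(batch, "batch_result"))
    stop_invalid("batch must be a batch_result")
  if (!inherits(config, "bottleneck_config"))
    stop_invalid("config must be a bottleneck_config")
  if (config$n_spikein > 0L &&
      length(config$pool_fractions) != length(batch$rho_final))
    stop_invalid("pool_fractions length must match the species count")
  draw <- function() {
    quantum <- env$rho0 / config$n_cells
    raw <- batch$rho_final / quantum
    counts <- floor(raw)
    counts <- counts + (runif(length(raw)) < (raw - counts))
    resident_n <- config$n_cells - config$n_spikein
    if (sum(counts) < resident_n)
      stop_invalid("population too small to sample: ", sum(counts),
                   " cells available, ", resident_n, " required")
    res <- rmvhyper1(counts, resident_n)
    if (config$n_spikein > 0L)
      res <- res + rmultinom(1L, config$n_spikein,
                             config$pool_fractions)[, 1L]
    as.integer(res)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Stochastic serial dilution with bottlenecks and spike-in migration
#'
#' Runs `n_batches` growth-dilution cycles, applying
#' [bottleneck_sample()] at every dilution, and averages the inoculum
#' composition over the post-burn-in batches.  Fully reproducible from
#' `config$seed`.
#'
#' @param inoculum0 initial densities (rescaled to total `env$rho0`).
#' @param strategies a [strategy_set()].
#' @param env a [nutrient_env()].
#' @param config a [bottleneck_config()].
#' @param n_batches number of batches to run.
#' @param burn_in batches discarded before averaging (default half).
#' @param batch a [batch_control()].
#' @return An object of class `stochastic_result`: `mean_fractions`
#'   (average post-burn-in inoculum composition), `rho_star`
#'   (`mean_fractions * rho0`), `diversity` (summary of the average
#'   composition), `me_series` (per-batch effective species), and
#'   `counts` (the n_batches x species history of sampled cells).
#' @export
run_stochastic <- function(inoculum0, strategies, env, config,
                           n_batches, burn_in = floor(n_batches / 2),
                           batch = batch_control()) {
  validate_strategy_set(strategies)
  n_batches <- as.integer(n_batches); burn_in <- as.integer(burn_in)
  if (n_batches <= burn_in)
    stop_invalid("n_batches must exceed burn_in")
  m <- nrow(strategies$alpha)
  rho0 <- env$rho0
  quantum <- rho0 / config$n_cells

  counts_hist <- matrix(NA_integer_, n_batches, m,
                        dimnames = list(NULL, strategies$labels))
  with_seed(config$seed, {
    inoc <- rho0 * inoculum0 / sum(inoculum0)
    for (b in seq_len(n_batches)) {
      res <- run_batch(inoc, strategies, env, batch)
      counts <- bottleneck_sample(res, config, env)
      counts_hist[b, ] <- counts
      inoc <- counts * quantum
    }
  })

  fractions <- counts_hist / config$n_cells
  post <- (burn_in + 1L):n_batches
  mean_fractions <- colMeans(fractions[post, , drop = FALSE])
  me_series <- apply(fractions, 1L, function(f)
    effective_species(f, 1)$m_e)

  structure(list(mean_fractions = mean_fractions,
                 rho_star = rho0 * mean_fractions,
                 diversity = effective_species(mean_fractions, 1),
                 me_series = me_series, counts = counts_hist,
                 burn_in = burn_in, config = config),
            class = "stochastic_result")
}

#' @export
print.stochastic_result <- function(x, ...) {
  cat("Stochastic serial dilution:", nrow(x$counts), "batches,",
      x$config$n_cells, "cells per inoculum (",
      x$config$n_spikein, "spike-in )\n")
  cat("  post-burn-in effective species m_e =",
      signif(x$diversity$m_e, 6), "\n")
  invisible(x)
}

#' Per-batch nutrient supply schedule
#'
#' `"mixed"` supplies the same bolus composition every batch.
#' `"alternating"` supplies a single pure nutrient per batch, cycling with
#' period `cycle_length` so that the long-run proportions match
#' `env$supply_fraction` (each fraction times `cycle_length` must be a
#' whole number of batches).
#'
#' @param env a [nutrient_env()].
#' @param schedule `"mixed"` or `"alternating"`.
#' @param cycle_length cycle length in batches (alternating only).
#' @return An object of class `bolus_schedule` with elements `period` and
#'   `supply(b)`, the composition supplied to batch `b`.
#' @examples
#' env <- nutrient_env(c0 = 1, supply_fraction = c(0.5, 0.5),
#'                     K = 1, rho0 = 1e-3)
#' sch <- bolus_schedule(env, "alternating", cycle_length = 2)
#' sch$supply(1); sch$supply(2)
#' @export
bolus_schedule <- function(env, schedule = c("mixed", "alternating"),
                           cycle_length = NULL) {
  schedule <- match.arg(schedule)
  if (schedule == "mixed") {
    sf <- env$supply_fraction
    return(structure(list(type = "mixed", period = 1L,
                          supply = function(b) sf),
                     class = "bolus_schedule"))
  }
  if (is.null(cycle_length))
    stop_invalid("alternating schedule requires cycle_length")
  L <- as.integer(cycle_length)
  counts <- env$supply_fraction * L
  if (any(abs(counts - round(counts)) > 1e-9))
    stop_invalid("supply proportions are not representable by a cycle of ",
                 "length ", L)
  counts <- as.integer(round(counts))
  seq_idx <- rep(seq_len(env$p), counts)
  p <- env$p
  structure(list(type = "alternating", period = L,
                 supply = function(b) {
                   i <- seq_idx[((b - 1L) %% L) + 1L]
                   f <- numeric(p); f[i] <- 1; f
                 }),
            class = "bolus_schedule")
}
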