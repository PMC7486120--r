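#' Specification of a diversity-versus-bolus-size sweep
#'
#' Describes a grid of (bolus size, supply composition) points over which
#' a community of equally spaced strategies is run to steady state and
#' its diversity recorded.  Variants select the model flavour: the
#' baseline single-trophic model, unequal Monod constants or yields,
#' cross-feeding (supply only Nutrient 2, with the composition parameter
#' interpreted as the target byproduct fraction of Nutrient 1, i.e.
#' \eqn{\Gamma = \phi/(1-\phi)}), stochastic bottlenecks with spike-in,
#' or alternating single-nutrient bolus cycles.
#'
#' @param variant one of `"baseline"`, `"unequal_K"`, `"unequal_Y"`,
#'   `"crossfeed"`, `"stochastic"`, `"alternating"`.
#' @param c0_grid positive bolus sizes (log-spaced by convention).
#' @param supply_compositions first-nutrient supply fractions (for
#'   `"crossfeed"`: target Nutrient-1 byproduct fractions, < 1).
#' @param m number of equally spaced strategies (default 21).
#' @param rho0 inoculum density.
#' @param K,Y Monod constants and yields (length 2).
#' @param yield_normalized interpret compositions as yield-normalized
#'   (composition \eqn{\phi} maps to supply fraction
#'   \eqn{(\phi/Y_1) / (\phi/Y_1 + (1-\phi)/Y_2)})?
#' @param epsilon budget-noise standard deviation (stochastic variant).
#' @param bottleneck a [bottleneck_config()] (stochastic variant).
#' @param n_batches,n_seeds stochastic run length and number of
#'   independent replicate seeds (means and ranges are reported).
#' @param cycle_length cycle length for the alternating variant.
#' @param seed base seed; per-point seeds are derived from it and the
#'   grid-point index so results do not depend on execution order.
#' @param protocol a [protocol_control()] for deterministic variants.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(variant = c("baseline", "unequal_K", "unequal_Y",
                                   "crossfeed", "stochastic",
                                   "alternating"),
                       c0_grid = 10^seq(-4, 4, length.out = 25),
                       supply_compositions = c(0.05, 0.1, 0.2, 0.3,
                                               0.4, 0.5),
                       m = 21L, rho0 = 1e-3, K = c(1, 1), Y = c(1, 1),
                       yield_normalized = FALSE, epsilon = 0,
                       bottleneck = NULL, n_batches = 1000L,
                       n_seeds = 3L, cycle_length = 2L, seed = 1L,
                       protocol = protocol_control()) {
  variant <- match.arg(variant)
  if (length(c0_grid) < 1L || any(c0_grid <= 0))
    stop_invalid("c0_grid must be non-empty and positive")
  if (length(supply_compositions) < 1L)
    stop_invalid("supply_compositions must be non-empty")
  if (variant == "crossfeed" && any(supply_compositions >= 1))
    stop_invalid("crossfeed compositions are Nutrient-1 fractions < 1")
  if (variant == "stochastic" && is.null(bottleneck))
    stop_invalid("stochastic variant requires a bottleneck_config")
  structure(list(variant = variant, c0_grid = as.numeric(c0_grid),
                 supply_compositions = as.numeric(supply_compositions),
                 m = as.integer(m), rho0 = rho0,
                 K = rep_len(as.numeric(K), 2L),
                 Y = rep_len(as.numeric(Y), 2L),
                 yield_normalized = yield_normalized, epsilon = epsilon,
                 bottleneck = bottleneck,
                 n_batches = as.integer(n_batches),
                 n_seeds = as.integer(n_seeds),
                 cycle_length = as.integer(cycle_length),
                 seed = as.integer(seed), protocol = protocol),
            class = "sweep_spec")
}

# Environment and supply for one grid point of a sweep.
sweep_point_env <- function(spec, c0, comp) {
  if (spec$variant == "crossfeed") {
    gamma <- comp / (1 - comp)
    return(nutrient_env(c0 = c0, supply_fraction = c(0, 1), K = spec$K,
                        Y = spec$Y, byproduct = byproduct_matrix(gamma),
                        rho0 = spec$rho0))
  }
  x <- comp
  if (spec$yield_normalized) {
    w <- c(comp / spec$Y[1L], (1 - comp) / spec$Y[2L])
    x <- w[1L] / sum(w)
  }
  nutrient_env(c0 = c0, supply_fraction = c(x, 1 - x), K = spec$K,
               Y = spec$Y, rho0 = spec$rho0)
}

#' Run a diversity sweep
#'
#' Runs every (c0, composition) grid point of a [sweep_spec()]
#' independently — the community is 21 (or `spec$m`) equally spaced
#' strategies with equal initial inocula summing to `rho0` — and collects
#' one row per point with the steady-state diversity and abundances.
#' Failed or non-converged points are recorded, never dropped.
#'
#' @param spec a [sweep_spec()].
#' @param verbose print one line per grid point?
#' @return A `data.frame` of class `sweep_table` with columns `variant`,
#'   `c0`, `c0_over_K` (referenced to `K[2]`), `composition`,
#'   `converged`, `batches_used`, `m_e` (plus `m_e_lo`/`m_e_hi` ranges
#'   over replicate seeds for the stochastic variant), `error`, and one
#'   abundance column per species.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  if (!inherits(spec, "sweep_spec")) stop_invalid("spec must be a sweep_spec")
  strategies <- equally_spaced_strategies(spec$m)
  grid <- expand.grid(c0 = spec$c0_grid, comp = spec$supply_compositions,
                      KEEP.OUT.ATTRS = FALSE)
  inoc0 <- rep(1, spec$m)

  rows <- lapply(seq_len(nrow(grid)), function(g) {
    c0 <- grid$c0[g]; comp <- grid$comp[g]
    point_seed <- (spec$seed + 7919L * g) %% .Machine$integer.max
    out <- list(variant = spec$variant, c0 = c0,
                c0_over_K = c0 / spec$K[2L], composition = comp,
                converged = NA, batches_used = NA_integer_,
                m_e = NA_real_, m_e_lo = NA_real_, m_e_hi = NA_real_,
                error = NA_character_)
    abund <- setNames(rep(NA_real_, spec$m), strategies$labels)
    res <- tryCatch({
      env <- sweep_point_env(spec, c0, comp)
      if (spec$variant == "stochastic") {
        strat <- if (spec$epsilon > 0)
          sample_budget_noise(strategies, spec$epsilon, seed = point_seed)
        else strategies
        mes <- numeric(spec$n_seeds)
        acc <- 0
        for (r in seq_len(spec$n_seeds)) {
          cfg <- spec$bottleneck
          cfg$seed <- (point_seed + r) %% .Machine$integer.max
          sr <- run_stochastic(inoc0, strat, env, cfg, spec$n_batches)
          mes[r] <- sr$diversity$m_e
          acc <- acc + sr$mean_fractions
        }
        mf <- acc / spec$n_seeds
        list(converged = TRUE, batches = spec$n_batches * spec$n_seeds,
             abund = env$rho0 * mf,
             m_e = mean(mes), lo = min(mes), hi = max(mes))
      } else {
        sched <- if (spec$variant == "alternating")
          bolus_schedule(env, "alternating", spec$cycle_length) else NULL
        ss <- run_to_steady_state(inoc0, strategies, env,
                                  control = spec$protocol,
                                  schedule = sched)
        list(converged = ss$converged, batches = ss$batches_used,
             abund = ss$rho_star, m_e = ss$diversity$m_e,
             lo = NA_real_, hi = NA_real_)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error <- conditionMessage(res)
      out$converged <- FALSE
    } else {
      out$converged <- res$converged
      out$batches_used <- res$batches
      out$m_e <- res$m_e; out$m_e_lo <- res$lo; out$m_e_hi <- res$hi
      abund[] <- res$abund
    }
    if (verbose)
      cat(sprintf("c0=%g comp=%g m_e=%.4g %s\n", c0, comp, out$m_e,
                  if (isTRUE(out$converged)) "" else "[not converged]"))
    c(out, as.list(abund))
  })

  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

#' Preset sweep configurations
#'
#' A catalog of ready-made [sweep_spec()]s for the canonical study
#' conditions:
#' \describe{
#'   \item{`fig3C`}{baseline: 21 equally spaced strategies, equal inocula
#'     summing to \eqn{\rho_0/K = 10^{-3}}, six supply compositions with
#'     first-nutrient fractions 0.05-0.5.}
#'   \item{`fig4A`}{unequal affinities: \eqn{K_1 = 10^{-3}},
#'     \eqn{K_2 = \rho_0 = 1}; compositions span both halves of the
#'     simplex since the nutrient symmetry is broken.}
#'   \item{`fig4C`}{unequal yields: \eqn{Y_1 = 10}, \eqn{Y_2 = \rho_0 =
#'     1}, compositions yield-normalized.}
#'   \item{`fig5A`}{cross-feeding: only Nutrient 2 supplied, Nutrient 1 a
#'     byproduct at target fractions 0.05-0.5.}
#'   \item{`fig6A`}{stochastic bottleneck: 1008 cells per inoculum, 958
#'     resident + 50 spike-in from 21 equally abundant strategies.}
#'   \item{`fig6C`}{as `fig6A` with species-specific enzyme budgets,
#'     \eqn{\epsilon = 0.1}.}
#' }
#'
#' @param name preset name; omit to get the whole named list.
#' @param seed base seed stored in the returned spec(s).
#' @return A `sweep_spec`, or a named list of them when `name` is `NULL`.
#' @export
fixture_configs <- function(name = NULL, seed = 1L) {
  pool <- rep(1 / 21, 21)
  both_halves <- c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                   0.6, 0.7, 0.8, 0.9, 0.95)
  presets <- list(
    fig3C = sweep_spec("baseline", rho0 = 1e-3, seed = seed),
    fig4A = sweep_spec("unequal_K", K = c(1e-3, 1), rho0 = 1,
                       supply_compositions = both_halves, seed = seed),
    fig4C = sweep_spec("unequal_Y", Y = c(10, 1), rho0 = 1,
                       supply_compositions = both_halves,
                       yield_normalized = TRUE, seed = seed),
    fig5A = sweep_spec("crossfeed", rho0 = 1e-3, seed = seed),
    fig6A = sweep_spec("stochastic", rho0 = 1e-3,
                       bottleneck = bottleneck_config(1008L, 50L, pool,
                                                      seed = seed),
                       seed = seed),
    fig6C = sweep_spec("stochastic", rho0 = 1e-3, epsilon = 0.1,
                       bottleneck = bottleneck_config(1008L, 50L, pool,
                                                      seed = seed),
                       seed = seed))
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop_invalid("unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", "))
  presets[[name]]
}
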