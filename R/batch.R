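#' Integration options for a single batch
#'
#' Controls the within-batch ODE solve.  The solver is `deSolve::lsodar`
#' (adaptive, implicit-capable, with event location by root-finding), with
#' the per-nutrient Monod integrals, consumption and production ledgers
#' carried as additional quadrature states of the same solve.
#'
#' Exact depletion takes infinite time (the nutrient tail decays
#' exponentially), so a batch is terminated when the total remaining
#' *consumable* nutrient falls below `depletion_fraction` times the total
#' eventually-consumable supply (initial bolus plus byproducts).  In
#' `"fixed_time"` mode the batch instead stops at `t_batch` regardless of
#' remaining nutrient (incomplete depletion).
#'
#' @param rtol relative integration tolerance (default 1e-10).
#' @param atol absolute tolerance on concentration and quadrature states
#'   (default 1e-14); biomass states are controlled relatively.
#' @param depletion_fraction termination threshold as a fraction of total
#'   consumable supply (default 1e-9).
#' @param mode `"depletion"` (run until nutrients are exhausted) or
#'   `"fixed_time"`.
#' @param t_batch batch duration, required in `"fixed_time"` mode.
#' @param t_max safety cap on integration time in depletion mode.
#' @param save_trajectory sample the trajectory (second pass over
#'   `n_trajectory` time points)?
#' @param n_trajectory number of sampled time points.
#' @return A list of class `batch_control`.
#' @export
batch_control <- function(rtol = 1e-10, atol = 1e-14,
                          depletion_fraction = 1e-9,
                          mode = c("depletion", "fixed_time"),
                          t_batch = NULL, t_max = 1e12,
                          save_trajectory = FALSE, n_trajectory = 201L) {
  mode <- match.arg(mode)
  if (mode == "fixed_time" &&
      (is.null(t_batch) || !is.numeric(t_batch) || t_batch <= 0))
    stop_invalid("fixed_time mode requires a positive t_batch")
  structure(list(rtol = rtol, atol = atol,
                 depletion_fraction = depletion_fraction, mode = mode,
                 t_batch = t_batch, t_max = t_max,
                 save_trajectory = save_trajectory,
                 n_trajectory = as.integer(n_trajectory)),
            class = "batch_control")
}

# Total nutrient that will eventually be consumed, per consumable nutrient:
# solves C = c_init + Gamma_cc C.  Errors if the byproduct matrix would
# regenerate nutrients without loss (spectral radius >= 1).
total_consumable_supply <- function(c_init, byproduct, consumable) {
  cc <- which(consumable)
  if (length(cc) == 0L) return(numeric(0))
  G <- byproduct[cc, cc, drop = FALSE]
  if (any(G > 0)) {
    ev <- max(abs(eigen(G, only.values = TRUE)$values))
    if (ev >= 1 - 1e-12)
      stop_invalid("byproduct matrix has spectral radius >= 1; ",
                   "total consumable nutrient would diverge")
  }
  as.numeric(solve(diag(length(cc)) - G, c_init[cc]))
}

#' Run one batch of growth to nutrient depletion
#'
#' Integrates the coupled consumer-resource dynamics
#' \deqn{\dot c_i = -\sum_\sigma \rho_\sigma \Big(j_{\sigma,i} -
#'       \sum_{i'} \Gamma_{i,i'} j_{\sigma,i'}\Big), \qquad
#'       \dot \rho_\sigma = \rho_\sigma \sum_i Y_i j_{\sigma,i},}
#' with Monod uptake \eqn{j_{\sigma,i} = \alpha_{\sigma,i} c_i/(K_i+c_i)},
#' from inoculation until the depletion event (or a fixed duration).  With
#' unit yields and no byproducts this reduces to the conservative system
#' in which total biomass plus total nutrient is constant and the final
#' total biomass is \eqn{\rho_0 + c_0}.
#'
#' The per-nutrient Monod integrals \eqn{I_i = \int_0^{t_f} c_i/(K_i+c_i)
#' \, dt} are accumulated as quadrature states; the fold increase of every
#' species over the batch is \eqn{\exp(\sum_i \alpha_{\sigma,i} Y_i I_i)}.
#'
#' @param inoculum non-negative initial biomass densities, one per species
#'   (positive total); species with zero inoculum are carried through
#'   unchanged.
#' @param strategies a [strategy_set()].
#' @param env a [nutrient_env()]; `env$supply_fraction` and `env$c0`
#'   define the bolus.
#' @param control a [batch_control()].
#' @return An object of class `batch_result` with elements `rho_final`,
#'   `t_f`, `I`, `consumed`, `produced`, `inoculum`, `supply`,
#'   `terminated_by`, optional `trajectory` (a data.frame), plus the
#'   `strategies` and `env` used.
#' @examples
#' env <- nutrient_env(c0 = 1, supply_fraction = 1, K = 1, rho0 = 1e-3)
#' res <- run_batch(1e-3, strategy_set(matrix(1, 1, 1)), env)
#' sum(res$rho_final)   # rho0 + c0 = 1.001
#' @export
run_batch <- function(inoculum, strategies, env,
                      control = batch_control()) {
  validate_strategy_set(strategies)
  inoculum <- as.numeric(inoculum)
  m_all <- nrow(strategies$alpha)
  p <- ncol(strategies$alpha)
  if (length(inoculum) != m_all)
    stop_invalid("inoculum must have one entry per species")
  if (any(!is.finite(inoculum)) || any(inoculum < 0))
    stop_invalid("inoculum must be finite and non-negative")
  if (sum(inoculum) <= 0)
    stop_invalid("all-zero inoculum: nothing to grow")
  if (env$p != p)
    stop_invalid("environment and strategies disagree on nutrient count")

  active <- which(inoculum > 0)
  alpha <- strategies$alpha[active, , drop = FALSE]
  m <- length(active)
  c_init <- env$c0 * env$supply_fraction
  consumable <- colSums(alpha) > 0

  if (control$mode == "depletion") {
    tot <- total_consumable_supply(c_init, env$byproduct, consumable)
    if (sum(tot) <= 0)
      stop_invalid("no consumable nutrient supplied; depletion unreachable")
    thresh <- control$depletion_fraction * sum(tot)
    t_end <- control$t_max
  } else {
    thresh <- 0
    t_end <- control$t_batch
  }

  parms <- c(m, p, thresh, env$K, env$Y, as.double(env$byproduct),
             as.double(alpha), as.double(consumable))
  y0 <- c(inoculum[active], c_init, numeric(3L * p))
  atol <- c(rep(1e-300, m), rep(control$atol, 4L * p))

  .C("batch_set_np", as.integer(length(parms)), PACKAGE = "serialdil")
  sol <- if (control$mode == "depletion") {
    deSolve::lsodar(y = y0, times = c(0, t_end), func = "batch_derivs",
                    parms = parms, dllname = "serialdil",
                    initfunc = "batch_initmod", rootfunc = "batch_root",
                    nroot = 1L, rtol = control$rtol, atol = atol,
                    maxsteps = 1e5)
  } else {
    deSolve::lsodar(y = y0, times = c(0, t_end), func = "batch_derivs",
                    parms = parms, dllname = "serialdil",
                    initfunc = "batch_initmod", rtol = control$rtol,
                    atol = atol, maxsteps = 1e5)
  }

  t_f <- unname(sol[nrow(sol), 1L])
  if (control$mode == "depletion") {
    troot <- attr(sol, "troot")
    if (is.null(troot) || length(troot) == 0L || is.na(troot[1L]))
      stop("batch integration reached t_max = ", control$t_max,
           " without depleting; last state retained in the condition",
           call. = FALSE)
    t_f <- troot[1L]
  }

  fin <- unname(sol[nrow(sol), -1L])
  rho_final <- inoculum
  rho_final[active] <- fin[seq_len(m)]
  c_final <- pmax(fin[m + seq_len(p)], 0)
  I <- fin[m + p + seq_len(p)]
  consumed <- fin[m + 2L * p + seq_len(p)]
  produced <- fin[m + 3L * p + seq_len(p)]

  trajectory <- NULL
  if (isTRUE(control$save_trajectory)) {
    times <- seq(0, t_f, length.out = control$n_trajectory)
    tr <- deSolve::lsodar(y = y0, times = times, func = "batch_derivs",
                          parms = parms, dllname = "serialdil",
                          initfunc = "batch_initmod", rtol = control$rtol,
                          atol = atol, maxsteps = 1e5)
    trajectory <- as.data.frame(tr[, seq_len(1L + m + p), drop = FALSE])
    names(trajectory) <- c("time", strategies$labels[active],
                           paste0("c", seq_len(p)))
  }

  structure(list(rho_final = rho_final, t_f = t_f, I = I,
                 consumed = consumed, produced = produced,
                 c_final = c_final, inoculum = inoculum,
                 supply = c_init,
                 terminated_by = if (control$mode == "depletion")
                   "depletion" else "fixed_time",
                 trajectory = trajectory,
                 strategies = strategies, env = env),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat("Batch result:", length(x$rho_final), "species,",
      length(x$supply), "nutrients\n")
  cat("  terminated by", x$terminated_by, "at t_f =",
      format(x$t_f, digits = 6), "\n")
  cat("  total biomass:", format(sum(x$inoculum), digits = 6), "->",
      format(sum(x$rho_final), digits = 6), "\n")
  cat("  Monod integrals I:", paste(signif(x$I, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Export a sampled batch trajectory as CSV
#'
#' @param result a `batch_result` run with `save_trajectory = TRUE`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(result, path) {
  if (is.null(result$trajectory))
    stop_invalid("batch was run without save_trajectory = TRUE")
  utils::write.csv(result$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Cross-feeding production/consumption audit
#'
#' For a batch run to depletion, audits the byproduct ledger.  In the
#' canonical bitrophic setup (two nutrients, only Nutrient 2 supplied,
#' byproduct matrix `byproduct_matrix(gamma)`), the time-integrated
#' production of Nutrient 1 equals \eqn{\Gamma c_2(0)}, the total
#' consumable nutrient over the batch is \eqn{(\Gamma+1) c_2(0)}, and
#' Nutrient 1's share of the total is \eqn{\Gamma/(1+\Gamma)}.
#'
#' @param result a `batch_result` terminated by depletion.
#' @param env the [nutrient_env()] of the run (defaults to the one stored
#'   in `result`).
#' @return A list with `consumed`, `produced`, `supplied`, the expected
#'   production `expected_produced` (= byproduct matrix applied to the
#'   consumption ledger), `total_consumable`, and `share` (each nutrient's
#'   fraction of total consumable supply).
#' @export
crossfeed_ledger <- function(result, env = result$env) {
  if (!inherits(result, "batch_result"))
    stop_invalid("result must be a batch_result")
  if (result$terminated_by != "depletion")
    stop_invalid("audit requires a batch run to depletion, not fixed_time")
  expected <- as.numeric(env$byproduct %*% result$consumed)
  total <- result$supply + result$produced
  list(consumed = result$consumed, produced = result$produced,
       supplied = result$supply, expected_produced = expected,
       total_consumable = total, share = total / sum(total))
}
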