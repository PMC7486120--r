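#' Effective number of species
#'
#' Summarizes a steady-state composition by the Shannon diversity
#' \eqn{S = -\sum_\sigma P_\sigma \ln P_\sigma} (in nats, with the
#' convention \eqn{x \ln x \to 0} as \eqn{x \to 0}) and the effective
#' number of species \eqn{m_e = e^S}, where
#' \eqn{P_\sigma = \rho^*_\sigma(0)/\rho_0}.  `m_e` equals the species
#' count exactly when abundances are uniform and 1 for a monoculture.
#'
#' @param rho_star non-negative steady-state abundances.
#' @param rho0 total inoculum density; `sum(rho_star)` must match it to
#'   within `tol` (relative).
#' @param tol relative tolerance on the total (default 1e-6).
#' @return An object of class `diversity_summary` with elements `P`
#'   (relative abundances), `S` (Shannon entropy, nats) and `m_e`.
#' @examples
#' effective_species(rep(1, 21), 21)$m_e   # 21
#' effective_species(c(0.9, 0.1), 1)$m_e   # about 1.384
#' @export
effective_species <- function(rho_star, rho0 = sum(rho_star),
                              tol = 1e-6) {
  rho_star <- as.numeric(rho_star)
  if (any(!is.finite(rho_star)) || any(rho_star < 0))
    stop_invalid("rho_star must be finite and non-negative")
  tot <- sum(rho_star)
  if (tot <= 0)
    stop_invalid("all-zero abundance vector: diversity undefined")
  if (abs(tot - rho0) > tol * rho0)
    stop_invalid("sum(rho_star) differs from rho0 beyond tolerance")
  P <- rho_star / rho0
  pos <- P[P > 0]
  S <- -sum(pos * log(pos))
  structure(list(P = P, S = S, m_e = exp(S)),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("Shannon diversity S =", signif(x$S, 6),
      "nats; effective species m_e =", signif(x$m_e, 6), "\n")
  invisible(x)
}
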