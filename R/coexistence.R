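#' Chemostat-limit steady-state residuals
#'
#' In the small-bolus limit \eqn{c_0 \ll K} the serial-dilution steady
#' state coincides with the chemostat steady state, and to first order in
#' \eqn{c_0/K} the inoculum abundances satisfy, for every species,
#' \deqn{\frac{c_0}{\rho_0} = \sum_i \frac{\alpha_{\sigma,i}\, c_i(0)}
#'       {\sum_{\sigma'} \alpha_{\sigma',i}\, \rho_{\sigma'}(0)}.}
#' This function evaluates the per-species deviation from that balance,
#' relative to \eqn{c_0/\rho_0}; a valid chemostat-limit steady state has
#' all residuals near zero.
#'
#' Dividing the balance by the depletion time \eqn{t_f} gives the average
#' supply rates \eqn{s_i = c_i(0)/t_f} and the per-biomass total supply
#' rate \eqn{\tilde\delta = c_0/(\rho_0 t_f)}, the serial-dilution
#' analogues of a chemostat's supply and dilution rates; these are filled
#' in when a `batch` at the same state is supplied.
#'
#' @param inoculum positive species abundances at the start of a batch.
#' @param strategies a [strategy_set()] with exact trade-offs
#'   (`epsilon = 0`).
#' @param env a [nutrient_env()].
#' @param batch optional `batch_result` from the same state, used to
#'   report `s` and `delta_tilde`.
#' @return An object of class `chemostat_view` with elements `residuals`
#'   (relative, per species), `s`, `delta_tilde`.
#' @export
chemostat_residual <- function(inoculum, strategies, env, batch = NULL) {
  validate_strategy_set(strategies)
  if (strategies$epsilon != 0)
    stop_invalid("chemostat-limit balance assumes exact trade-offs ",
                 "(epsilon = 0)")
  inoculum <- as.numeric(inoculum)
  if (length(inoculum) != nrow(strategies$alpha) || any(inoculum < 0) ||
      sum(inoculum) <= 0)
    stop_invalid("inoculum must be non-negative with positive sum")
  c_init <- env$c0 * env$supply_fraction
  Tt <- drop(crossprod(strategies$alpha, inoculum))   # total allocation
  if (any(Tt == 0 & c_init > 0))
    stop_invalid("a supplied nutrient has zero total enzyme allocation; ",
                 "the balance is undefined")
  term <- ifelse(c_init > 0, c_init / Tt, 0)
  ratio <- env$c0 / sum(inoculum)
  residuals <- (drop(strategies$alpha %*% term) - ratio) / ratio

  s <- delta_tilde <- NULL
  if (!is.null(batch)) {
    s <- batch$supply / batch$t_f
    delta_tilde <- env$c0 / (sum(batch$inoculum) * batch$t_f)
  }
  structure(list(residuals = residuals, s = s, delta_tilde = delta_tilde),
            class = "chemostat_view")
}

#' Fold increase of an infinitesimal invader
#'
#' Given a resident community's batch at its serial-dilution steady
#' state, the fold increase over that batch of an infinitesimally rare
#' invader with allocation row `invader` is
#' \eqn{\exp(\sum_i \alpha_i Y_i I_i)}, computed from the resident
#' batch's Monod integrals (the invader does not perturb the trajectory).
#' The invader can invade iff its fold exceeds the residents' common
#' steady-state fold \eqn{(\rho_0 + c_0)/\rho_0}.
#'
#' @param resident_batch a `batch_result` at steady state; an error is
#'   raised if the per-species folds are not equal to within `stale_tol`
#'   (the scaling relation of a steady state).
#' @param invader allocation row (same budget convention as residents).
#' @param env a [nutrient_env()] (defaults to the batch's).
#' @param stale_tol relative spread of resident folds tolerated.
#' @return A list with `fold`, `resident_fold`, and `can_invade`.
#' @export
invasion_fold <- function(resident_batch, invader,
                          env = resident_batch$env, stale_tol = 1e-6) {
  if (!inherits(resident_batch, "batch_result"))
    stop_invalid("resident_batch must be a batch_result")
  act <- resident_batch$inoculum > 0
  folds <- resident_batch$rho_final[act] / resident_batch$inoculum[act]
  if ((max(folds) - min(folds)) / mean(folds) > stale_tol)
    stop_invalid("stale state: resident batch violates the steady-state ",
                 "scaling relation (fold spread ",
                 format((max(folds) - min(folds)) / mean(folds)), ")")
  invader <- as.numeric(invader)
  if (length(invader) != length(resident_batch$I))
    stop_invalid("invader must have one allocation per nutrient")
  fold <- exp(sum(invader * env$Y * resident_batch$I))
  resident_fold <- sum(resident_batch$rho_final) /
    sum(resident_batch$inoculum)
  list(fold = fold, resident_fold = resident_fold,
       can_invade = fold > resident_fold)
}

#' Remapped coexistence boundary of a strategy
#'
#' The remapped boundary of a resident strategy at a given bolus size is
#' the supply composition for which, over the course of one of the
#' resident's batches, all nutrients are equally valuable — so that any
#' unit-budget strategy invades neutrally.  Equal value is measured by
#' the yield-weighted Monod integrals \eqn{Y_i I_i} (equal \eqn{I_i} for
#' unit yields), which makes the invader fold
#' \eqn{\exp(\sum_i \alpha_i Y_i I_i)} strategy-independent at the
#' boundary.  The resident state is a single batch of the resident alone
#' inoculated at `rho0` (a monoculture's serial-dilution steady state is
#' reached in one batch).
#'
#' Nutrients outside the strategy's support are never consumed by the
#' resident, so their value grows without bound as the depletion
#' threshold is tightened; the equal-value supply therefore puts zero
#' weight on them.  In particular single-nutrient specialists map to
#' their own vertex — specialists are not remapped.
#'
#' For two nutrients the boundary is found by bracketed scalar
#' root-finding on the supply composition (the value difference is
#' monotone, so the interior root is unique when bracketed); for more
#' nutrients a simplex-parameterized Nelder-Mead minimizes the spread of
#' the \eqn{Y_i I_i}.
#'
#' @param strategy allocation row (unit budget).
#' @param env a [nutrient_env()]; `c0` and `rho0` set the bolus and
#'   inoculum at which remapping is evaluated.
#' @param tol root tolerance on the composition (default 1e-10).
#' @param batch a [batch_control()] for the underlying batch solves.
#' @return An object of class `remap_result` with elements `strategy`,
#'   `boundary` (a simplex composition), `converged`, `residual` (the
#'   remaining equal-value imbalance), `at_vertex`.
#' @examples
#' env <- nutrient_env(c0 = 1, supply_fraction = c(0.5, 0.5),
#'                     K = 1, rho0 = 1e-3)
#' remapped_boundary(c(0.5, 0.5), env)$boundary   # (0.5, 0.5): unmoved
#' @export
remapped_boundary <- function(strategy, env, tol = 1e-10,
                              batch = batch_control()) {
  strategy <- as.numeric(strategy)
  p <- length(strategy)
  if (p != env$p) stop_invalid("strategy and env disagree on p")
  if (any(strategy < 0) || sum(strategy) <= 0)
    stop_invalid("strategy must be non-negative with positive sum")
  support <- which(strategy > 0)
  sset <- strategy_set(matrix(strategy, 1L), budget = sum(strategy))

  value <- function(supply) {
    e <- env; e$supply_fraction <- supply
    res <- run_batch(env$rho0, sset, e, batch)
    env$Y * res$I
  }

  if (length(support) == 1L) {
    boundary <- numeric(p); boundary[support] <- 1
    return(structure(list(strategy = strategy, boundary = boundary,
                          converged = TRUE, residual = 0,
                          at_vertex = TRUE),
                     class = "remap_result"))
  }

  if (p == 2L) {
    g <- function(x) { v <- value(c(x, 1 - x)); v[1L] - v[2L] }
    lo <- 1e-12; hi <- 1 - 1e-12
    glo <- g(lo); ghi <- g(hi)
    if (glo >= 0 || ghi <= 0) {
      # value difference does not change sign: boundary at a vertex
      x <- if (glo >= 0) 0 else 1
      return(structure(list(strategy = strategy, boundary = c(x, 1 - x),
                            converged = TRUE,
                            residual = if (glo >= 0) glo else ghi,
                            at_vertex = TRUE),
                       class = "remap_result"))
    }
    root <- uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi, tol = tol)
    return(structure(list(strategy = strategy,
                          boundary = c(root$root, 1 - root$root),
                          converged = abs(root$f.root) < 1e-8,
                          residual = root$f.root, at_vertex = FALSE),
                     class = "remap_result"))
  }

  # p >= 3: optimize over the support's simplex via a softmax chart
  k <- length(support)
  spread <- function(z) {
    w <- exp(c(0, z)); w <- w / sum(w)
    supply <- numeric(p); supply[support] <- w
    v <- value(supply)[support]
    sum((v - mean(v))^2)
  }
  z0 <- log(strategy[support][-1L] / strategy[support][1L])
  opt <- optim(z0, spread, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-14))
  w <- exp(c(0, opt$par)); w <- w / sum(w)
  boundary <- numeric(p); boundary[support] <- w
  v <- value(boundary)[support]
  residual <- max(abs(v - mean(v)))
  structure(list(strategy = strategy, boundary = boundary,
                 converged = residual < 1e-8, residual = residual,
                 at_vertex = FALSE),
            class = "remap_result")
}

#' @export
print.remap_result <- function(x, ...) {
  cat("Remapped coexistence boundary\n")
  cat("  strategy:", paste(signif(x$strategy, 6), collapse = ", "), "\n")
  cat("  boundary:", paste(signif(x$boundary, 6), collapse = ", "),
      if (x$at_vertex) "(vertex)" else "", "\n")
  cat("  residual:", format(x$residual, digits = 3), "\n")
  invisible(x)
}

#' Convex-hull membership of a supply composition
#'
#' Tests whether the nutrient supply lies within the convex hull of the
#' strategy compositions on the simplex — the condition under which an
#' arbitrarily large number of species can coexist in the chemostat
#' limit.  Membership is decided by linear feasibility: non-negative
#' weights reproducing the supply (since both the points and the supply
#' lie on the composition simplex, feasible weights automatically sum
#' to 1).  Boundary points count as contained (closed hull).
#'
#' @param points matrix of simplex compositions, one row per strategy (a
#'   single composition may be given as a vector).
#' @param supply simplex composition to test.
#' @param tol feasibility tolerance (default 1e-9).
#' @return An object of class `hull_result`: `contains`, `weights`
#'   (convex-combination weights when contained), and `margin` — the
#'   signed distance to the hull boundary in composition units (exact for
#'   2 nutrients, Euclidean on the ternary embedding for 3, `NA` beyond).
#' @examples
#' convex_hull_contains(rbind(c(0, 1), c(1, 0)), c(0.3, 0.7))
#' @export
convex_hull_contains <- function(points, supply, tol = 1e-9) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  supply <- as.numeric(supply)
  p <- ncol(points)
  if (length(supply) != p)
    stop_invalid("supply and points disagree on the number of nutrients")
  if (nrow(points) < 1L) stop_invalid("need at least one point")

  A <- t(points)
  w <- nnls_lh(A, supply)
  resid <- max(abs(drop(A %*% w) - supply))
  contains <- resid < tol
  weights <- if (contains && sum(w) > 0) w / sum(w) else NULL

  margin <- NA_real_
  if (p == 2L) {
    margin <- min(supply[1L] - min(points[, 1L]),
                  max(points[, 1L]) - supply[1L])
  } else if (p == 3L) {
    margin <- ternary_margin(points, supply, contains)
  }
  structure(list(contains = contains, weights = weights, margin = margin),
            class = "hull_result")
}

# Signed Euclidean distance (on the standard ternary embedding) from the
# supply point to the hull boundary of 3-nutrient compositions.
ternary_margin <- function(points, supply, contains) {
  embed <- function(x) cbind(x[, 2L] + 0.5 * x[, 3L], sqrt(3) / 2 * x[, 3L])
  P <- embed(points)
  q <- drop(embed(matrix(supply, 1L)))
  h <- chull(P)
  V <- P[h, , drop = FALSE]
  nv <- nrow(V)
  if (nv == 1L) {
    d <- sqrt(sum((q - V[1L, ])^2))
  } else {
    seg_dist <- function(a, b, q) {
      ab <- b - a
      t <- sum((q - a) * ab) / max(sum(ab^2), .Machine$double.xmin)
      t <- min(max(t, 0), 1)
      sqrt(sum((q - (a + t * ab))^2))
    }
    d <- min(vapply(seq_len(nv), function(i)
      seg_dist(V[i, ], V[(i %% nv) + 1L, ], q), numeric(1L)))
  }
  if (contains) d else -d
}

#' Supply interval of mutual invasibility for two species
#'
#' For two nutrients, the supplies at which two species can each invade
#' the other — and hence stably coexist — form the interval bracketed by
#' their remapped coexistence boundaries.  In the chemostat limit the
#' window coincides with the strategies themselves; near \eqn{c_0
#' \approx K} it contracts inwards.
#'
#' @param strategyA,strategyB allocation rows with
#'   `strategyA[1] < strategyB[1]`.
#' @param env a [nutrient_env()].
#' @param ... passed to [remapped_boundary()].
#' @return A list with `lower` and `upper` (first-nutrient supply
#'   fractions), `empty` (TRUE when the boundaries cross), and the two
#'   `remap_result`s.
#' @export
coexistence_window <- function(strategyA, strategyB, env, ...) {
  strategyA <- as.numeric(strategyA); strategyB <- as.numeric(strategyB)
  if (env$p != 2L || length(strategyA) != 2L || length(strategyB) != 2L)
    stop_invalid("coexistence_window is defined for two nutrients")
  if (isTRUE(all.equal(strategyA, strategyB)))
    stop_invalid("identical strategies: coexistence window degenerate")
  if (strategyA[1L] >= strategyB[1L])
    stop_invalid("require strategyA[1] < strategyB[1]")
  bA <- remapped_boundary(strategyA, env, ...)
  bB <- remapped_boundary(strategyB, env, ...)
  lower <- bA$boundary[1L]; upper <- bB$boundary[1L]
  list(lower = lower, upper = upper, empty = lower > upper,
       boundaryA = bA, boundaryB = bB)
}
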