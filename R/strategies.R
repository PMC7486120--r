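#' Enzyme-allocation strategy sets
#'
#' A strategy set holds the community's enzyme-allocation matrix
#' \eqn{\alpha}: one row per species, one column per nutrient, entries
#' non-negative.  Metabolic trade-offs constrain each row to sum to the
#' species' enzyme budget \eqn{E + \epsilon \xi_\sigma}, where
#' \eqn{\xi_\sigma} is a standard-normal draw and \eqn{\epsilon = 0}
#' ("exact trade-offs") makes every budget exactly \eqn{E}.
#'
#' @param alpha numeric matrix of non-negative allocations, rows = species,
#'   columns = nutrients.
#' @param budget common enzyme budget \eqn{E} (default 1).
#' @param epsilon standard deviation of the budget noise (default 0).
#' @param xi per-species budget-noise draws; a zero vector when
#'   `epsilon = 0`.
#' @param labels character vector of species identifiers; defaults to
#'   `"s1", "s2", ...`.
#'
#' @return An object of class `strategy_set` with elements `alpha`,
#'   `budget`, `epsilon`, `xi`, `labels`.
#'
#' @examples
#' s <- strategy_set(rbind(c(0.3, 0.7), c(0.8, 0.2)))
#' s$alpha
#' @export
strategy_set <- function(alpha, budget = 1, epsilon = 0, xi = NULL,
                         labels = NULL) {
  alpha <- as.matrix(alpha)
  storage.mode(alpha) <- "double"
  m <- nrow(alpha)
  p <- ncol(alpha)
  if (m < 1L || p < 1L)
    stop_invalid("alpha must have at least one row and one column")
  if (!is.numeric(budget) || length(budget) != 1L || budget <= 0)
    stop_invalid("budget must be a single positive number")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop_invalid("epsilon must be a single non-negative number")
  if (is.null(xi)) xi <- numeric(m)
  if (length(xi) != m)
    stop_invalid("xi must have one entry per species")
  if (is.null(labels)) labels <- paste0("s", seq_len(m))
  if (length(labels) != m)
    stop_invalid("labels must have one entry per species")

  obj <- structure(
    list(alpha = unname(alpha), budget = budget, epsilon = epsilon,
         xi = as.numeric(xi), labels = as.character(labels)),
    class = "strategy_set")
  validate_strategy_set(obj)
  obj
}

#' Validate a strategy set
#'
#' Checks non-negativity of the allocation matrix and that every row sum
#' matches its budget \eqn{E + \epsilon \xi_\sigma} to within `tol`.
#'
#' @param x a `strategy_set`.
#' @param tol absolute tolerance on row sums (default 1e-9).
#' @return `x`, invisibly; errors if invalid.
#' @export
validate_strategy_set <- function(x, tol = 1e-9) {
  if (!inherits(x, "strategy_set")) stop_invalid("not a strategy_set")
  if (any(!is.finite(x$alpha)) || any(x$alpha < 0))
    stop_invalid("all allocations must be finite and non-negative")
  budgets <- x$budget + x$epsilon * x$xi
  if (any(budgets <= 0))
    stop_invalid("every species budget must be strictly positive")
  rs <- rowSums(x$alpha)
  if (any(abs(rs - budgets) > tol))
    stop_invalid("row sums of alpha must equal the species budgets ",
                 "(max deviation ", format(max(abs(rs - budgets))), ")")
  invisible(x)
}

#' @export
print.strategy_set <- function(x, ...) {
  cat("Strategy set:", nrow(x$alpha), "species on", ncol(x$alpha),
      "nutrients\n")
  cat("  budget E =", x$budget, " epsilon =", x$epsilon, "\n")
  k <- min(nrow(x$alpha), 6L)
  mat <- round(x$alpha[seq_len(k), , drop = FALSE], 4)
  rownames(mat) <- x$labels[seq_len(k)]
  print(mat)
  if (nrow(x$alpha) > k) cat("  ...", nrow(x$alpha) - k, "more species\n")
  invisible(x)
}

#' Equally spaced strategies on the nutrient simplex
#'
#' For two nutrients, returns `m` strategies whose first-nutrient
#' allocations are `0, 1/(m-1), ..., 1`, i.e. the two specialists plus
#' evenly interpolated generalists.  For `p > 2`, returns the regular
#' simplex lattice with `m` points per edge: all allocations
#' `(k1, ..., kp)/(m-1)` with non-negative integers `k` summing to `m-1`
#' (so the total count is `choose(m+p-2, p-1)`).
#'
#' @param m number of strategies per simplex edge (>= 2); for `p = 2` this
#'   is the total number of strategies.
#' @param p number of nutrients (default 2).
#' @return A `strategy_set` with exact trade-offs (`epsilon = 0`, `E = 1`).
#' @examples
#' equally_spaced_strategies(3)$alpha
#' @export
equally_spaced_strategies <- function(m, p = 2) {
  if (!is.numeric(m) || length(m) != 1L || m < 2 || m != round(m))
    stop_invalid("m must be an integer >= 2 (spacing undefined otherwise)")
  if (!is.numeric(p) || length(p) != 1L || p < 2 || p != round(p))
    stop_invalid("p must be an integer >= 2")
  m <- as.integer(m); p <- as.integer(p)
  if (p == 2L) {
    x <- seq(0, 1, length.out = m)
    alpha <- cbind(x, 1 - x)
  } else {
    grid <- simplex_lattice(m - 1L, p)
    alpha <- grid / (m - 1L)
  }
  strategy_set(alpha)
}

# All p-part compositions of n (non-negative integers summing to n),
# ordered lexicographically; rows of the (n+1 choose ...) lattice.
simplex_lattice <- function(n, p) {
  if (p == 1L) return(matrix(n, 1L, 1L))
  out <- NULL
  for (k in 0:n) {
    sub <- simplex_lattice(n - k, p - 1L)
    out <- rbind(out, cbind(k, sub))
  }
  unname(out)
}

#' Sample species-specific enzyme budgets
#'
#' Relaxes exact trade-offs by drawing budgets \eqn{E + \epsilon
#' \xi_\sigma} with \eqn{\xi_\sigma} standard normal, then rescaling each
#' species' allocation row multiplicatively to its new budget (allocation
#' fractions are preserved).  Draws that would produce a non-positive
#' budget are rejected and redrawn; the number of rejections is recorded
#' in the `rejections` attribute.
#'
#' @param strategies a `strategy_set` to rescale.
#' @param epsilon budget-noise standard deviation (>= 0).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return A new `strategy_set` with the sampled `xi` and rescaled rows.
#' @examples
#' s <- sample_budget_noise(equally_spaced_strategies(5), 0.1, seed = 1)
#' rowSums(s$alpha) - (1 + 0.1 * s$xi)
#' @export
sample_budget_noise <- function(strategies, epsilon, seed) {
  validate_strategy_set(strategies)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop_invalid("epsilon must be a single non-negative number")
  m <- nrow(strategies$alpha)
  E <- strategies$budget
  rejections <- 0L
  xi <- with_seed(seed, {
    draw <- numeric(m)
    for (s in seq_len(m)) {
      repeat {
        z <- rnorm(1L)
        if (E + epsilon * z > 0) { draw[s] <- z; break }
        rejections <- rejections + 1L
      }
    }
    draw
  })
  budgets <- E + epsilon * xi
  fractions <- strategies$alpha / rowSums(strategies$alpha)
  out <- strategy_set(fractions * budgets, budget = E, epsilon = epsilon,
                      xi = xi, labels = strategies$labels)
  attr(out, "rejections") <- rejections
  out
}
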