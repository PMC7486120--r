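# Lawson-Hanson active-set non-negative least squares:
#   minimize ||A x - b||_2  subject to  x >= 0.
# Used for the convex-hull membership test; no NNLS/LP solver is part of
# the package's dependency set, and the problems here are tiny (p x n
# with p, n at most a few dozen), so the textbook algorithm suffices.
nnls_lh <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * n
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      s[P][is.na(s[P])] <- 0
      if (all(s[P] > tol)) break
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}
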