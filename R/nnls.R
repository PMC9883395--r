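#' Non-negative least squares (Lawson-Hanson)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0` by the active-set method
#' of Lawson and Hanson. Used to project spectra onto a fixed basis matrix.
#'
#' @param A numeric matrix (`m x n`).
#' @param b numeric vector of length `m`.
#' @param tol dual-feasibility tolerance.
#' @param max_iter iteration cap (default `3 * n`).
#' @return list with `x` (the solution, `>= 0`) and `residual_norm`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10, max_iter = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- max(3L * n, 30L)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))            # gradient of the unconstrained fit
  scale <- max(abs(w), 1)
  outer_it <- 0L
  while (any(!passive & w > tol * scale) && outer_it < max_iter) {
    outer_it <- outer_it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      fit <- qr.coef(qr(A[, P, drop = FALSE]), b)
      fit[is.na(fit)] <- 0
      z[P] <- fit
      if (all(z[P] > tol)) {
        x <- z
        break
      }
      neg <- P[z[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + .Machine$double.xmin))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)))
}
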