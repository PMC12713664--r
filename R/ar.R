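# AR(p) temporal noise: Yule-Walker estimation, exact whitening via the
# Levinson-Durbin recursion, and dense covariance construction for oracles.
#
# For an AR(p) process the T x T covariance is Toeplitz and its inverse is
# banded with bandwidth p; the Cholesky factor L of the precision (L' L =
# Sigma^{-1}) applies in O(T p) per series: the first p rows use the
# increasing-order one-step predictors from Levinson-Durbin, the remaining
# rows the stationary AR filter scaled by the innovation SD.

#' Yule-Walker AR(p) estimation
#'
#' Estimates AR coefficients and innovation variance from sample
#' autocovariances. Stationarity is enforced: if any root of the AR
#' polynomial falls on or inside the unit circle the coefficient vector is
#' shrunk (roots scaled inward) with a warning.
#'
#' @param x Numeric series (e.g., GLM residuals), or a matrix whose columns
#'   are series.
#' @param p AR order (>= 0). `p = 0` returns no coefficients and the sample
#'   variance as innovation variance.
#' @param demean Subtract the sample mean first (default `TRUE`).
#' @return For a vector, a list with `phi` (length `p`), `sigma2`
#'   (innovation variance) and `degenerate` flag; for a matrix, a list with
#'   `phi` (`p x V`) and `sigma2` (length `V`).
#' @export
yule_walker_ar <- function(x, p = 1L, demean = TRUE) {
  p <- as.integer(p)
  if (p < 0L) stopf("AR order must be >= 0")
  if (is.matrix(x)) {
    fits <- apply(x, 2L, yule_walker_ar, p = p, demean = demean,
                  simplify = FALSE)
    return(list(
      phi = matrix(vapply(fits, function(f) as.numeric(f$phi), numeric(p)),
                   nrow = p),
      sigma2 = vapply(fits, `[[`, numeric(1), "sigma2"),
      degenerate = vapply(fits, `[[`, logical(1), "degenerate")))
  }
  n <- length(x)
  if (p > 0L && n <= 10L * p)
    stopf("series too short (T = %d) for AR order p = %d", n, p)
  if (demean) x <- x - mean(x)
  c0 <- sum(x^2) / n
  if (c0 <= .Machine$double.eps * 100) {
    return(list(phi = numeric(p), sigma2 = 0, degenerate = TRUE))
  }
  if (p == 0L) return(list(phi = numeric(0), sigma2 = c0, degenerate = FALSE))
  g <- sapply(seq_len(p), function(k) sum(x[seq_len(n - k)] * x[-seq_len(k)]) / n)
  G <- stats::toeplitz(c(c0, g))[seq_len(p), seq_len(p), drop = FALSE]
  phi <- drop(solve(G, g))
  phi <- enforce_stationarity(phi)
  sigma2 <- max(c0 - sum(phi * g), c0 * 1e-8)
  list(phi = phi, sigma2 = sigma2, degenerate = FALSE)
}

# Shrink AR coefficients until all roots of 1 - phi_1 z - ... - phi_p z^p lie
# outside the unit circle.
#' @keywords internal
#' @noRd
enforce_stationarity <- function(phi, margin = 0.998) {
  if (!length(phi)) return(phi)
  rho <- max(Mod(1 / polyroot(c(1, -phi))))  # largest inverse root
  if (rho < margin) return(phi)
  warnf("non-stationary AR estimate (max inverse root %.3f); shrunk", rho)
  c_fac <- (margin * 0.999) / rho
  phi * c_fac^seq_along(phi)
}

#' @keywords internal
#' @noRd
is_stationary_ar <- function(phi) {
  !length(phi) || all(Mod(polyroot(c(1, -phi))) > 1)
}

# Theoretical autocovariances gamma_0..gamma_{lag} of an AR(p) process,
# solving the Yule-Walker system in the forward direction.
#' @keywords internal
#' @noRd
ar_acov <- function(phi, sigma2, lag) {
  p <- length(phi)
  if (p == 0L) return(c(sigma2, rep(0, lag)))
  # unknowns gamma_0..gamma_p from:
  #   gamma_k - sum_j phi_j gamma_{|k-j|} = sigma2 * 1{k=0}, k = 0..p
  A <- diag(p + 1)
  for (k in 0:p) for (j in seq_len(p))
    A[k + 1, abs(k - j) + 1] <- A[k + 1, abs(k - j) + 1] - phi[j]
  g <- solve(A, c(sigma2, rep(0, p)))
  if (lag > p) for (k in (p + 1):lag)
    g <- c(g, sum(phi * g[k - seq_len(p) + 1]))
  g[seq_len(lag + 1)]
}

#' Dense AR(p) Toeplitz covariance (oracle helper)
#'
#' @param phi AR coefficients.
#' @param sigma2 Innovation variance.
#' @param n Matrix dimension (time points).
#' @return `n x n` Toeplitz covariance matrix.
#' @export
ar_covariance <- function(phi, sigma2, n) {
  stats::toeplitz(ar_acov(phi, sigma2, n - 1L))
}

# Levinson-Durbin on theoretical autocovariances: one-step predictor
# coefficients of orders 0..p and prediction error variances.
#' @keywords internal
#' @noRd
levinson_durbin <- function(gam, p) {
  v <- gam[1]
  a <- list(numeric(0))
  vs <- v
  if (p > 0) for (k in seq_len(p)) {
    ak1 <- a[[k]]
    num <- gam[k + 1] - if (k > 1) sum(ak1 * gam[k:2]) else 0
    kap <- num / v
    ak <- c(ak1 - kap * rev(ak1), kap)
    v <- v * (1 - kap^2)
    a[[k + 1]] <- ak
    vs <- c(vs, v)
  }
  list(coef = a, pev = vs)
}

#' Whiten series under an AR(p) noise model
#'
#' Applies the banded Cholesky factor `L` of the AR precision (`L' L =
#' Sigma^{-1}`), so that if `x` has covariance `Sigma` the result has identity
#' covariance. Rows `1..p` use the exact increasing-order Levinson-Durbin
#' predictors; rows `p+1..T` the stationary AR filter divided by the
#' innovation SD. Cost is `O(T p)` per column.
#'
#' @param x Series vector or `T x m` matrix (columns whitened jointly with
#'   the same model).
#' @param phi AR coefficients (stationary).
#' @param sigma2 Innovation variance (> 0).
#' @return Whitened vector/matrix of the same shape.
#' @export
ar_whiten <- function(x, phi, sigma2) {
  phi <- as.numeric(phi)
  if (!is_stationary_ar(phi)) stopf("non-stationary AR coefficients")
  if (sigma2 <= 0) stopf("innovation variance must be positive")
  xm <- as.matrix(x)
  n <- nrow(xm)
  p <- length(phi)
  if (p == 0L) {
    w <- xm / sqrt(sigma2)
    return(if (is.matrix(x)) w else drop(w))
  }
  ld <- levinson_durbin(ar_acov(phi, sigma2, p), p)
  w <- matrix(0, n, ncol(xm))
  for (t in seq_len(min(p, n))) {
    k <- t - 1L
    # predictor: sum_j a_j x_{t-j}; coef[[k+1]][j] multiplies x_{t-j}
    pred <- if (k > 0) {
      aj <- ld$coef[[k + 1]]
      colSums(xm[t - seq_len(k), , drop = FALSE] * aj)
    } else 0
    w[t, ] <- (xm[t, ] - pred) / sqrt(ld$pev[k + 1])
  }
  if (n > p) {
    idx <- (p + 1L):n
    acc <- xm[idx, , drop = FALSE]
    for (j in seq_len(p)) acc <- acc - phi[j] * xm[idx - j, , drop = FALSE]
    w[idx, ] <- acc / sqrt(sigma2)
  }
  if (is.matrix(x)) w else drop(w)
}

# Log-determinant of the AR(p) covariance of dimension n (sum of log
# prediction error variances along the Levinson-Durbin ramp).
#' @keywords internal
#' @noRd
ar_logdet <- function(phi, sigma2, n) {
  p <- length(phi)
  if (p == 0L) return(n * log(sigma2))
  ld <- levinson_durbin(ar_acov(phi, sigma2, p), p)
  sum(log(ld$pev[seq_len(min(p, n))])) + max(0L, n - p) * log(sigma2)
}
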