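# Low-rank thin-plate regression spline bases on arbitrary point clouds.
#
# For a parcel with V locations x_1..x_V in R^d (d = 2 or 3), the full
# thin-plate spline solution space is spanned by the radial kernel functions
# eta(||x - x_i||) plus the affine polynomials {1, x_1, ..., x_d}. The
# low-rank regression-spline basis keeps the M - (d+1) leading eigenvectors
# (by |eigenvalue|) of the V x V kernel matrix E, E_ij = eta(||x_i - x_j||),
# together with the polynomial block, and orthonormalizes. The basis is used
# unpenalized; M itself is the smoothing control (selected by BIC upstream).

#' Thin-plate spline radial kernel
#'
#' `eta(r) = r^2 log(r)` for `d = 2` (with `eta(0) = 0`) and `eta(r) = -r` for
#' `d = 3` — the standard second-order thin-plate radial bases up to a
#' positive constant, which is irrelevant here because the basis columns are
#' orthonormalized after eigendecomposition.
#'
#' @param r Non-negative distances.
#' @param d Spatial dimension, 2 or 3.
#' @return Kernel values, same length as `r`.
#' @export
tps_kernel <- function(r, d) {
  if (!(d %in% c(2L, 3L))) stopf("unsupported spatial dimension d = %s", d)
  if (any(r < 0)) stopf("distances must be non-negative")
  if (d == 2L) ifelse(r > 0, r^2 * log(r), 0) else -r
}

#' Construct a low-rank thin-plate regression spline basis
#'
#' Builds the `V x M` orthonormal basis `S` for a parcel from its coordinates:
#' eigendecompose the radial-kernel matrix, keep the `M - (d+1)` leading
#' eigenvectors by absolute eigenvalue, and orthonormalize jointly with the
#' affine polynomial block (constant plus linear coordinates), polynomials
#' first so that bases are nested in `M`. Eigenvector signs are fixed by
#' making the largest-magnitude entry positive, so the construction is
#' deterministic given `coords` and `M`.
#'
#' @param coords `V x d` coordinate matrix, `d` in {2, 3}. Duplicated rows are
#'   collapsed (with a warning) before the eigendecomposition; the returned
#'   basis still has one row per input location.
#' @param M Basis dimension, `d + 1 <= M <=` number of distinct locations.
#' @return Object of class `"tps_basis"`: list with `S` (`V x M`, orthonormal
#'   columns), `M`, `null_dim = d + 1`, `eigen_spectrum` (retained
#'   eigenvalues), and `coords`.
#' @examples
#' xy <- cbind(runif(40), runif(40))
#' b <- tps_basis(xy, M = 8)
#' crossprod(b$S)[1:3, 1:3] # identity
#' @export
tps_basis <- function(coords, M) {
  Q <- tps_basis_full(coords, M_max = M)
  if (ncol(Q$Q) < M)
    stopf("requested M = %d exceeds the attainable rank %d", M, ncol(Q$Q))
  structure(list(S = Q$Q[, seq_len(M), drop = FALSE], M = as.integer(M),
                 null_dim = Q$null_dim,
                 eigen_spectrum = utils::head(Q$eigenvalues, max(0L, M - Q$null_dim)),
                 coords = Q$coords),
            class = "tps_basis")
}

# Full priority-ordered orthonormal basis: polynomial block first, then kernel
# eigenvectors by decreasing |eigenvalue|, sequential Gram-Schmidt skipping
# near-dependent columns. Taking the first M columns yields the M-dimensional
# basis, so bases are nested across M.
#' @keywords internal
#' @noRd
tps_basis_full <- function(coords, M_max = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stopf("non-finite coordinates")
  d <- ncol(coords)
  if (!(d %in% c(2L, 3L))) stopf("unsupported spatial dimension d = %d", d)
  V <- nrow(coords)
  if (V < 1L) stopf("empty parcel")
  null_dim <- d + 1L
  M_max <- as.integer(M_max %||% V)
  if (M_max < null_dim)
    stopf("M (%d) must be at least the polynomial dimension d + 1 = %d",
          M_max, null_dim)
  if (M_max > V) stopf("M (%d) exceeds the number of locations V = %d", M_max, V)

  key <- apply(coords, 1L, paste, collapse = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("%d duplicated coordinate row(s) collapsed", sum(dup))
    if (M_max > sum(!dup))
      stopf("M (%d) exceeds the number of distinct locations %d",
            M_max, sum(!dup))
  }
  uid <- which(!dup)
  xu <- coords[uid, , drop = FALSE]
  map <- match(key, key[uid])
  Vu <- nrow(xu)

  E <- tps_kernel(as.matrix(stats::dist(xu)), d)
  eig <- eigen(E, symmetric = TRUE)
  ord <- order(abs(eig$values), decreasing = TRUE)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }

  cand <- cbind(1, xu, vecs)[map, , drop = FALSE]  # back to all V rows
  # sequential Gram-Schmidt with drop of near-dependent columns
  Q <- matrix(0, V, M_max)
  kept <- 0L
  taken_eig <- integer(0)
  for (j in seq_len(ncol(cand))) {
    v <- cand[, j]
    nrm0 <- sqrt(sum(v^2))
    if (nrm0 == 0) next
    if (kept > 0L) {
      Qk <- Q[, seq_len(kept), drop = FALSE]
      v <- v - Qk %*% crossprod(Qk, v)
      v <- v - Qk %*% crossprod(Qk, v)  # second pass for stability
    }
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-9 * nrm0) next
    kept <- kept + 1L
    v <- v / nrm
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    Q[, kept] <- v
    if (j > null_dim) taken_eig <- c(taken_eig, j - null_dim)
    if (kept == M_max) break
  }
  if (kept < M_max)
    stopf("coordinates only support a basis of rank %d (< M = %d)", kept, M_max)
  list(Q = Q, null_dim = null_dim,
       eigenvalues = vals[taken_eig[taken_eig <= length(vals)]],
       coords = coords)
}

#' Project a field onto a spline basis
#'
#' Least-squares spline coefficients `argmin_g ||field - S g||`; with the
#' orthonormal basis this is simply `t(S) %*% field`.
#'
#' @param basis A `"tps_basis"`.
#' @param field Numeric vector of length `V` (or `V x m` matrix).
#' @return Coefficient vector of length `M` (or `M x m` matrix).
#' @export
project_field <- function(basis, field) {
  stopifnot(inherits(basis, "tps_basis"))
  field <- as.matrix(field)
  if (nrow(field) != nrow(basis$S))
    stopf("field length %d does not match V = %d", nrow(field), nrow(basis$S))
  assert_finite(field, "field")
  drop(crossprod(basis$S, field))
}

#' @export
print.tps_basis <- function(x, ...) {
  cat(sprintf("thin-plate regression spline basis: V = %d, M = %d (affine null space %d), d = %d\n",
              nrow(x$S), x$M, x$null_dim, ncol(x$coords)))
  invisible(x)
}
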