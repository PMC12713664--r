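# Gaussian kernel smoothing comparator and its closed-form bias/variance
# oracles.
#
# GKS smooths the observed BOLD series before GLM fitting:
#   y-tilde_v = sum_u w_{vu} y_u,  w_{vu} prop exp(-||v-u||^2 / (2 h^2)),
# weights truncated at `truncation * h` and renormalized to sum to one.
# Because the GLM is linear, E[beta-hat_GKS(v)] = sum_u w_{vu} beta_u — a
# spatial-average bias — and with iid N(0, sigma^2) noise the usual residual
# variance estimator is attenuated by the factor sum_u w_{vu}^2.

#' Gaussian kernel smoothing weights
#'
#' Row-stochastic sparse `V x V` weight matrix: row `v` holds the normalized
#' Gaussian weights over locations within `truncation * h` of `v` (always
#' including `v` itself, so isolated locations get weight 1 on themselves).
#'
#' @param coords `V x d` coordinates.
#' @param h Bandwidth (same units as `coords`), > 0.
#' @param truncation Support radius as a multiple of `h` (default 3).
#' @return A `dgCMatrix` with rows summing to 1.
#' @export
gks_weights <- function(coords, h, truncation = 3) {
  if (h <= 0) stopf("bandwidth h must be positive")
  coords <- as.matrix(coords)
  V <- nrow(coords)
  D2 <- as.matrix(stats::dist(coords))^2
  r2 <- (truncation * h)^2
  keep <- which(D2 <= r2, arr.ind = TRUE)
  w <- exp(-D2[keep] / (2 * h^2))
  W <- Matrix::sparseMatrix(i = keep[, 1], j = keep[, 2], x = w,
                            dims = c(V, V))
  rs <- Matrix::rowSums(W)
  Matrix::Diagonal(x = 1 / rs) %*% W
}

#' Kernel weights at one location
#'
#' @param coords `V x d` coordinates.
#' @param v Location index.
#' @param h Bandwidth.
#' @param truncation Support radius multiple.
#' @return Dense weight vector of length `V` summing to 1.
#' @export
kernel_weights <- function(coords, v, h, truncation = 3) {
  if (h <= 0) stopf("bandwidth h must be positive")
  coords <- as.matrix(coords)
  d2 <- colSums((t(coords) - coords[v, ])^2)
  w <- ifelse(d2 <= (truncation * h)^2, exp(-d2 / (2 * h^2)), 0)
  w / sum(w)
}

#' Smooth time series with a Gaussian kernel
#'
#' `Ytilde[, v] = sum_u w_{vu} Y[, u]` — linear in `Y`; a constant-in-space
#' input is reproduced exactly because the rows of `W` sum to one.
#'
#' @param Y `T x V` matrix.
#' @param W Weight matrix from [gks_weights()] (or any row-stochastic matrix).
#' @return Smoothed `T x V` matrix.
#' @export
gks_smooth <- function(Y, W) {
  Y <- as.matrix(Y)
  if (ncol(Y) != nrow(W)) stopf("Y has %d columns but W is %d x %d",
                                ncol(Y), nrow(W), ncol(W))
  as.matrix(Matrix::tcrossprod(Y, W))
}

#' Closed-form bias of GKS activation estimates
#'
#' For any coefficient field `beta`, the expected GKS estimate at `v` is the
#' kernel average `sum_u w_{vu} beta_u`, so the bias is that average minus
#' `beta_v`; it vanishes iff `beta` is constant over the kernel support.
#'
#' @param W Row-stochastic weight matrix.
#' @param beta `V x m` coefficient field (or vector).
#' @return Bias field, same shape as `beta`.
#' @export
gks_bias <- function(W, beta) {
  beta <- as.matrix(beta)
  as.matrix(W %*% beta) - beta
}

#' Variance attenuation factor of GKS
#'
#' `sum_u w_{vu}^2` per location: the multiplicative downward bias of the
#' usual residual variance estimator after kernel smoothing with iid
#' homoskedastic noise. Equals 1 without smoothing and `1/m` for uniform
#' weights over `m` locations.
#'
#' @param W Row-stochastic weight matrix.
#' @return Numeric vector in `(0, 1]`, one entry per location.
#' @export
attenuation_factor <- function(W) {
  as.numeric(Matrix::rowSums(W^2))
}

#' Convert between FWHM and Gaussian bandwidth
#'
#' `FWHM = 2 sqrt(2 log 2) * h` (about `2.3548 h`); a bandwidth of 2.55
#' corresponds to FWHM 6.
#'
#' @param fwhm,h Value to convert.
#' @return Converted value.
#' @export
fwhm_to_bandwidth <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname fwhm_to_bandwidth
#' @export
bandwidth_to_fwhm <- function(h) h * (2 * sqrt(2 * log(2)))

#' Adaptive GKS: BIC bandwidth selection
#'
#' For each candidate bandwidth, the data are smoothed, the vertex GLM
#' refitted, and a parcel-level BIC computed; the bandwidth minimizing the
#' summed BIC over subjects is selected per parcel (smallest on ties).
#'
#' The BIC uses an effective-complexity correction: the per-location residual
#' variance is de-attenuated by the factor `sum_u w^2` (which would otherwise
#' fall spuriously with `h`), and the parameter count is `KB * V_eff` with
#' `V_eff = sum_v sum_u w_{vu}^2` (`= V` with no smoothing, shrinking as
#' neighborhoods pool).
#'
#' @param Y_list List of `T x V` matrices (subjects).
#' @param design Task design (`"fmri_design"` or matrix).
#' @param coords `V x d` coordinates.
#' @param parcels Length-`V` parcel labels.
#' @param h_grid Positive candidate bandwidths.
#' @param truncation Kernel support radius multiple.
#' @return List with `h` (named per-parcel selected bandwidth) and `bic`
#'   (parcels x grid matrix).
#' @export
agks_select_bandwidth <- function(Y_list, design, coords, parcels, h_grid,
                                  truncation = 3) {
  if (!length(h_grid)) stopf("empty bandwidth grid")
  if (any(h_grid <= 0)) stopf("bandwidths must be positive")
  h_grid <- sort(unique(h_grid))
  parcels <- as.factor(parcels)
  lev <- levels(parcels)
  bic_tab <- matrix(0, length(lev), length(h_grid),
                    dimnames = list(lev, as.character(h_grid)))
  for (g in seq_along(h_grid)) {
    W <- gks_weights(coords, h_grid[g], truncation)
    att <- attenuation_factor(W)
    for (s in seq_along(Y_list)) {
      pr <- project_out_nuisance(as.matrix(Y_list[[s]]), design)
      Ys <- gks_smooth(pr$Y, W)
      fit <- fit_vertex_glm(Ys, pr$X)
      T_vol <- nrow(Ys); KB <- ncol(pr$X)
      sig2 <- pmax(fit$sigma2 / att, .Machine$double.eps)
      for (pi in seq_along(lev)) {
        idx <- which(parcels == lev[pi])
        v_eff <- sum(att[idx])
        bic_tab[pi, g] <- bic_tab[pi, g] +
          sum(T_vol * log(sig2[idx])) + KB * v_eff * log(T_vol)
      }
    }
  }
  h_star <- apply(bic_tab, 1L, function(row)
    h_grid[which.min(row)])  # first minimum = smallest h on ties
  list(h = h_star, bic = bic_tab)
}
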