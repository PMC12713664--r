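# SPLASH: parcel-localized spline regression on GLM activation coefficients.
#
# Within a parcel with V locations, the stacked time-series model is
#   Y = Z P Phi Gamma + eps,  Z = I_V (x) X,  Phi = I_KB (x) S,
# with P the location-major -> basis-major permutation, S the V x M
# thin-plate regression spline basis and Gamma the KB*M spline coefficients.
# The FGLS estimator Gamma-hat = (A' Sigma^-1 A)^-1 A' Sigma^-1 Y (A = Z P Phi)
# is computed without materializing A, accumulating
#   A' Sigma^-1 A = sum_v (X' Sigma_v^-1 X) (x) (s_v s_v'),
#   A' Sigma^-1 Y = sum_v (X' Sigma_v^-1 y_v) (x) s_v,
# where s_v is row v of S and Sigma_v the AR(p) temporal covariance at v.
# With homoskedastic independent errors this reduces to OLS, and because S
# has orthonormal columns the OLS solution is simply Gamma_kl = S' beta_kl
# applied to the vertex-GLM coefficients.
#
# Coefficient ordering: Gamma stacks blocks (k, l)-major, each of length M;
# location-major index of beta is (v-1)*KB + kl, basis-major index is
# (kl-1)*V + v.

#' Fit the SPLASH model for one parcel
#'
#' Structured OLS or feasible-GLS fit of the parcel-localized spline model.
#' For `estimator = "fgls"`, per-location AR(p) noise models are estimated
#' from vertex-GLM residuals (unless supplied) and the generalized
#' least-squares normal equations are accumulated in Kronecker form.
#'
#' @param Y `T x V` time-series matrix for the parcel's locations.
#' @param X `T x KB` task design matrix (nuisance already projected out).
#' @param basis A [tps_basis()] for the parcel (orthonormal `V x M`).
#' @param estimator `"ols"` or `"fgls"`.
#' @param ar_order AR order for `"fgls"` (0..8).
#' @param noise Optional precomputed noise model: list with `phi` (`p x V`)
#'   and `sigma2` (length `V`).
#' @param vertex Optional precomputed [fit_vertex_glm()] result for `Y`.
#' @param dof_extra Extra per-location parameters already removed from the
#'   data (e.g., projected nuisance regressors); enters degrees of freedom.
#' @return Object of class `"splash_parcel_fit"`: `gamma` (`M x KB`),
#'   `beta_sp` (`V x KB`), `vertex_beta`, `var_gamma` (`KB*M` square),
#'   `var_beta_sp` (`V x KB`), `sigma2_hat` (OLS only), `noise`, `loglik`,
#'   `bic`, `M`, `estimator`, `n`, `k_par`.
#' @export
fit_splash_parcel <- function(Y, X, basis, estimator = c("ols", "fgls"),
                              ar_order = 1L, noise = NULL, vertex = NULL,
                              dof_extra = 0L) {
  estimator <- match.arg(estimator)
  Y <- as.matrix(Y); X <- as.matrix(X)
  S <- basis$S
  T_vol <- nrow(Y); V <- ncol(Y); KB <- ncol(X); M <- ncol(S)
  if (nrow(S) != V) stopf("basis has %d rows but Y has %d locations", nrow(S), V)
  if (KB * M >= T_vol * V)
    stopf("underdetermined parcel model: K*B*M = %d >= T*V = %d", KB * M, T_vol * V)
  if (is.null(vertex)) vertex <- fit_vertex_glm(Y, X)
  XtX <- crossprod(X)
  n <- T_vol * V
  k_par <- KB * M
  dof <- n - k_par - V * dof_extra

  if (estimator == "ols") {
    gamma <- unname(crossprod(S, vertex$beta))    # M x KB
    beta_sp <- S %*% gamma
    D <- vertex$beta - beta_sp
    rss <- sum(vertex$residuals^2) + sum((D %*% XtX) * D)
    sigma2_hat <- rss / dof
    sigma2_mle <- rss / n
    loglik <- -n / 2 * (log(2 * pi * sigma2_mle) + 1)
    XtX_inv <- chol2inv(chol(XtX))
    var_gamma <- sigma2_hat * kronecker(XtX_inv, diag(M))
    lev <- rowSums(S^2)
    var_beta_sp <- sigma2_hat * outer(lev, diag(XtX_inv))
    noise_out <- list(phi = matrix(0, 0L, V), sigma2 = rep(sigma2_hat, V),
                      order = 0L)
  } else {
    p <- as.integer(ar_order)
    if (is.null(noise)) {
      nm <- yule_walker_ar(vertex$residuals, p = p)
      noise <- list(phi = nm$phi, sigma2 = nm$sigma2)
    }
    if (is.null(dim(noise$phi))) noise$phi <- matrix(noise$phi, ncol = V)
    p <- nrow(noise$phi)
    N_mat <- matrix(0, KB * M, KB * M)
    C <- matrix(0, V, KB)      # whitened X' y per location
    quad <- num_logdet <- numeric(V)
    for (v in seq_len(V)) {
      s2v <- noise$sigma2[v]
      if (s2v <= 0) s2v <- mean(noise$sigma2[noise$sigma2 > 0]) %||% 1
      phiv <- noise$phi[, v]
      Xw <- ar_whiten(X, phiv, s2v)
      yw <- ar_whiten(Y[, v], phiv, s2v)
      sv <- S[v, ]
      N_mat <- N_mat + kronecker(crossprod(Xw), tcrossprod(sv))
      C[v, ] <- crossprod(Xw, yw)
      num_logdet[v] <- ar_logdet(phiv, s2v, T_vol)
    }
    rhs <- crossprod(S, C)                        # M x KB
    ch <- tryCatch(chol(N_mat), error = function(e)
      stopf("singular normal equations in parcel fit (M = %d, V = %d)", M, V))
    gamma_vec <- backsolve(ch, forwardsolve(t(ch), as.vector(rhs)))
    gamma <- matrix(gamma_vec, M, KB)
    beta_sp <- S %*% gamma
    # Gaussian log-likelihood under the fitted AR noise
    for (v in seq_len(V)) {
      s2v <- noise$sigma2[v]; if (s2v <= 0) s2v <- 1
      r <- Y[, v] - X %*% beta_sp[v, ]
      quad[v] <- sum(ar_whiten(r, noise$phi[, v], s2v)^2)
    }
    rss <- sum(quad)
    loglik <- -0.5 * sum(T_vol * log(2 * pi) + num_logdet + quad)
    var_gamma <- chol2inv(ch)
    var_beta_sp <- matrix(0, V, KB)
    for (kl in seq_len(KB)) {
      idx <- (kl - 1L) * M + seq_len(M)
      Vg <- var_gamma[idx, idx, drop = FALSE]
      var_beta_sp[, kl] <- rowSums((S %*% Vg) * S)
    }
    sigma2_hat <- NA_real_
    noise_out <- list(phi = noise$phi, sigma2 = noise$sigma2, order = p)
  }
  dimnames(beta_sp) <- list(NULL, colnames(vertex$beta))
  dimnames(var_beta_sp) <- dimnames(beta_sp)
  dimnames(gamma) <- list(NULL, colnames(vertex$beta))
  structure(list(
    gamma = gamma, beta_sp = beta_sp, vertex_beta = vertex$beta,
    var_gamma = var_gamma, var_beta_sp = var_beta_sp,
    sigma2_hat = sigma2_hat, noise = noise_out,
    loglik = loglik, rss = rss, n = n, k_par = k_par,
    bic = -2 * loglik + k_par * log(n),
    M = M, estimator = estimator), class = "splash_parcel_fit")
}

#' BIC of a fitted parcel model
#'
#' `BIC = -2 loglik + k log(n)` with `n = T*V` observations in the parcel and
#' `k = K*B*M` spline coefficients; the log-likelihood is Gaussian under the
#' fitted noise model (variance-concentrated for OLS).
#'
#' @param fit A `"splash_parcel_fit"`.
#' @return Numeric BIC.
#' @export
bic_score <- function(fit) {
  stopifnot(inherits(fit, "splash_parcel_fit"))
  fit$bic
}

#' @keywords internal
#' @noRd
default_M_grid <- function(V, null_dim, n_points = 8L, M_cap = 100L) {
  lo <- null_dim + 1L
  hi <- min(V, M_cap)
  if (hi <= lo) return(lo)
  sort(unique(pmax(lo, pmin(hi, round(exp(seq(log(lo), log(hi),
                                              length.out = n_points)))))))
}

# Residualize Y (and the task block) on nuisance regressors.
#' @keywords internal
#' @noRd
project_out_nuisance <- function(Y, design) {
  if (!inherits(design, "fmri_design") || is.null(design$nuisance))
    return(list(Y = Y, X = if (inherits(design, "fmri_design")) design$X else design,
                J = 0L))
  N <- design$nuisance
  qn <- qr(N)
  list(Y = Y - qr.fitted(qn, Y),
       X = design$X - qr.fitted(qn, design$X),
       J = ncol(N))
}

#' Fit SPLASH across all parcels for one subject
#'
#' The main model-fitting entry point. Splits the locations by parcel, builds
#' a thin-plate regression spline basis per parcel, fits the localized spline
#' model by OLS or AR(p) feasible GLS, and (optionally) selects the spatial
#' basis dimension `M` per parcel by BIC. Parcels too small to carry a spline
#' basis (fewer than `d + 3` locations) fall back to the vertex-wise GLM and
#' are flagged.
#'
#' @param Y `T x V` matrix of BOLD time series, columns in the same order as
#'   `coords` rows.
#' @param coords `V x d` coordinate matrix (`d` = 2 or 3).
#' @param parcels Length-`V` parcel labels (factor or character).
#' @param design An `"fmri_design"` (see [build_design()]) or plain task
#'   design matrix. Nuisance regressors, if present, are projected out of
#'   both `Y` and the task columns before spline fitting.
#' @param estimator `"ols"` or `"fgls"`.
#' @param ar_order AR order for FGLS noise (default 1; up to 8).
#' @param M Spline basis dimension: `NULL` (select by BIC over `M_grid`), a
#'   single number (shared cap, truncated per parcel), or a named vector with
#'   one entry per parcel level.
#' @param M_grid Candidate grid for BIC selection; default geometric grid
#'   from `d + 2` to `min(V_p, 100)` with ~8 points per parcel.
#' @param keep_data Keep `Y` (nuisance-residualized) in the object so
#'   [fitted()] and [residuals()] work (default `TRUE`).
#' @return Object of class `"splash"`. Key components: `coef` (`V x KB`
#'   smoothed activation coefficients, vertex order as input), `se` (their
#'   standard errors), `vertex_beta` (unsmoothed GLM coefficients), `M`
#'   (named per-parcel basis dimensions), `parcel_fits` (per-parcel details),
#'   `bic` (total).
#' @seealso [select_basis_dim()] for choosing a shared `M` across subjects,
#'   [splash_inference()] for group-level activation mapping.
#' @export
splash <- function(Y, coords, parcels, design, estimator = c("ols", "fgls"),
                   ar_order = 1L, M = NULL, M_grid = NULL, keep_data = TRUE) {
  estimator <- match.arg(estimator)
  Y <- as.matrix(Y); coords <- as.matrix(coords)
  V <- ncol(Y)
  if (nrow(coords) != V) stopf("coords rows (%d) != columns of Y (%d)",
                               nrow(coords), V)
  parcels <- as.factor(parcels)
  if (length(parcels) != V) stopf("parcel labels must have length V = %d", V)
  if (ar_order > 8L) stopf("ar_order capped at 8")
  pr <- project_out_nuisance(Y, design)
  Yr <- pr$Y; X <- pr$X; J <- pr$J
  KB <- ncol(X)
  d <- ncol(coords)
  null_dim <- d + 1L
  vertex_all <- fit_vertex_glm(Yr, X)
  labels <- if (inherits(design, "fmri_design")) design$labels else
    data.frame(condition = colnames(X) %||% paste0("c", seq_len(KB)), basis = 1L)

  lev <- levels(parcels)
  coef_mat <- se_mat <- matrix(NA_real_, V, KB)
  fits <- vector("list", length(lev)); names(fits) <- lev
  M_sel <- setNames(rep(NA_integer_, length(lev)), lev)
  for (pi in seq_along(lev)) {
    idx <- which(parcels == lev[pi])
    Vp <- length(idx)
    Yp <- Yr[, idx, drop = FALSE]
    vert_p <- list(beta = vertex_all$beta[idx, , drop = FALSE],
                   residuals = vertex_all$residuals[, idx, drop = FALSE],
                   sigma2 = vertex_all$sigma2[idx],
                   df_residual = vertex_all$df_residual,
                   XtX_inv = vertex_all$XtX_inv)
    if (Vp < null_dim + 2L) {
      # spline model undefined: vertex-GLM fallback
      coef_mat[idx, ] <- vert_p$beta
      se_mat[idx, ] <- sqrt(outer(vert_p$sigma2, diag(vertex_all$XtX_inv)))
      fits[[pi]] <- list(flag = "glm_fallback", M = NA_integer_, V = Vp)
      next
    }
    # candidate dimensions
    Ms <- if (is.null(M)) {
      M_grid %||% default_M_grid(Vp, null_dim)
    } else if (length(M) == 1L && is.null(names(M))) {
      min(as.integer(M), Vp)
    } else {
      mm <- M[[lev[pi]]]
      if (is.null(mm) || is.na(mm)) stopf("no M entry for parcel '%s'", lev[pi])
      min(as.integer(mm), Vp)
    }
    Ms <- pmin(pmax(as.integer(Ms), null_dim), Vp)
    Ms <- sort(unique(Ms))
    full <- tps_basis_full(coords[idx, , drop = FALSE], M_max = max(Ms))
    noise_p <- NULL
    if (estimator == "fgls" && ar_order > 0L) {
      nm <- yule_walker_ar(vert_p$residuals, p = ar_order)
      noise_p <- list(phi = nm$phi, sigma2 = nm$sigma2)
    }
    best <- NULL
    for (m in Ms) {
      basis_m <- structure(list(S = full$Q[, seq_len(m), drop = FALSE],
                                M = m, null_dim = full$null_dim,
                                coords = full$coords), class = "tps_basis")
      f <- fit_splash_parcel(Yp, X, basis_m, estimator = estimator,
                             ar_order = ar_order, noise = noise_p,
                             vertex = vert_p, dof_extra = J)
      if (is.null(best) || f$bic < best$bic) best <- f
    }
    coef_mat[idx, ] <- best$beta_sp
    se_mat[idx, ] <- sqrt(pmax(best$var_beta_sp, 0))
    M_sel[pi] <- best$M
    fits[[pi]] <- best
  }
  colnames(coef_mat) <- colnames(se_mat) <- colnames(X) %||%
    paste0(labels$condition, "_b", labels$basis)
  total_bic <- sum(vapply(fits, function(f)
    if (inherits(f, "splash_parcel_fit")) f$bic else 0, numeric(1)))
  structure(list(
    coef = coef_mat, se = se_mat, vertex_beta = vertex_all$beta,
    parcels = parcels, coords = coords, labels = labels,
    estimator = estimator, ar_order = as.integer(ar_order),
    M = M_sel, parcel_fits = fits, bic = total_bic,
    X = X, nuisance_df = J,
    Y = if (keep_data) Yr else NULL,
    call = match.call()), class = "splash")
}

#' Select a shared spline basis dimension per parcel across subjects
#'
#' For each candidate `M` the per-subject parcel BIC is summed over subjects;
#' the minimizer (smallest `M` on ties) is returned for each parcel, so the
#' whole group is fitted at a common spatial resolution.
#'
#' @param Y_list List of `T x V` matrices, one per subject.
#' @inheritParams splash
#' @return List with `M` (named integer vector per parcel) and `bic` (matrix
#'   parcels x grid of summed BIC values, `NA` where a candidate exceeds the
#'   parcel size).
#' @export
select_basis_dim <- function(Y_list, coords, parcels, design,
                             estimator = c("ols", "fgls"), ar_order = 1L,
                             M_grid = NULL) {
  estimator <- match.arg(estimator)
  parcels <- as.factor(parcels)
  lev <- levels(parcels)
  d <- ncol(as.matrix(coords)); null_dim <- d + 1L
  grid_all <- M_grid %||% default_M_grid(max(table(parcels)), null_dim)
  if (!length(grid_all)) stopf("empty M grid")
  grid_all <- sort(unique(as.integer(grid_all)))
  bic_tab <- matrix(NA_real_, length(lev), length(grid_all),
                    dimnames = list(lev, as.character(grid_all)))
  for (s in seq_along(Y_list)) {
    pr <- project_out_nuisance(as.matrix(Y_list[[s]]), design)
    vertex_all <- fit_vertex_glm(pr$Y, pr$X)
    for (pi in seq_along(lev)) {
      idx <- which(parcels == lev[pi])
      Vp <- length(idx)
      if (Vp < null_dim + 2L) next
      vert_p <- list(beta = vertex_all$beta[idx, , drop = FALSE],
                     residuals = vertex_all$residuals[, idx, drop = FALSE],
                     sigma2 = vertex_all$sigma2[idx],
                     df_residual = vertex_all$df_residual,
                     XtX_inv = vertex_all$XtX_inv)
      Ms <- pmin(pmax(as.integer(grid_all), null_dim), Vp)
      ok <- !duplicated(Ms)
      full <- tps_basis_full(as.matrix(coords)[idx, , drop = FALSE],
                             M_max = max(Ms))
      noise_p <- NULL
      if (estimator == "fgls" && ar_order > 0L) {
        nm <- yule_walker_ar(vert_p$residuals, p = ar_order)
        noise_p <- list(phi = nm$phi, sigma2 = nm$sigma2)
      }
      for (g in which(ok)) {
        m <- Ms[g]
        basis_m <- structure(list(S = full$Q[, seq_len(m), drop = FALSE],
                                  M = m, null_dim = full$null_dim,
                                  coords = full$coords), class = "tps_basis")
        f <- fit_splash_parcel(pr$Y[, idx, drop = FALSE], pr$X, basis_m,
                               estimator = estimator, ar_order = ar_order,
                               noise = noise_p, vertex = vert_p,
                               dof_extra = pr$J)
        bic_tab[pi, g] <- (if (is.na(bic_tab[pi, g])) 0 else bic_tab[pi, g]) + f$bic
      }
    }
  }
  M_star <- apply(bic_tab, 1L, function(row) {
    if (all(is.na(row))) return(NA_integer_)
    as.integer(names(row)[which.min(row)])  # which.min takes the first = smallest M
  })
  list(M = M_star, bic = bic_tab)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.splash <- function(x, ...) {
  cat(sprintf("SPLASH fit (%s%s): %d locations, %d parcel(s), %d task coefficient(s)\n",
              toupper(x$estimator),
              if (x$estimator == "fgls") sprintf(", AR(%d)", x$ar_order) else "",
              nrow(x$coef), nlevels(x$parcels), ncol(x$coef)))
  msel <- x$M[!is.na(x$M)]
  if (length(msel))
    cat(sprintf("  spline dimension M: median %g (range %d-%d)\n",
                stats::median(msel), min(msel), max(msel)))
  nfall <- sum(vapply(x$parcel_fits, function(f)
    identical(f$flag, "glm_fallback"), logical(1)))
  if (nfall) cat(sprintf("  %d small parcel(s) fell back to the vertex GLM\n", nfall))
  cat(sprintf("  total BIC: %.1f\n", x$bic))
  invisible(x)
}

#' @export
coef.splash <- function(object, smoothed = TRUE, ...) {
  if (smoothed) object$coef else object$vertex_beta
}

#' @export
fitted.splash <- function(object, ...) {
  object$X %*% t(object$coef)
}

#' @export
residuals.splash <- function(object, ...) {
  if (is.null(object$Y))
    stopf("fit was created with keep_data = FALSE; residuals unavailable")
  object$Y - fitted(object)
}

#' @export
summary.splash <- function(object, ...) {
  per_parcel <- data.frame(
    parcel = levels(object$parcels),
    V = as.integer(table(object$parcels)),
    M = as.integer(object$M),
    bic = vapply(object$parcel_fits, function(f)
      if (inherits(f, "splash_parcel_fit")) f$bic else NA_real_, numeric(1)),
    fallback = vapply(object$parcel_fits, function(f)
      identical(f$flag, "glm_fallback"), logical(1)),
    row.names = NULL)
  structure(list(per_parcel = per_parcel, estimator = object$estimator,
                 ar_order = object$ar_order, bic = object$bic,
                 KB = ncol(object$coef)), class = "summary.splash")
}

#' @export
print.summary.splash <- function(x, ...) {
  cat(sprintf("SPLASH (%s) parcel summary:\n", toupper(x$estimator)))
  print(x$per_parcel, row.names = FALSE)
  invisible(x)
}

#' Map of smoothed activation coefficients
#'
#' Plots one coefficient column of the fitted activation field against the
#' spatial coordinates: a colored scatter in 2D, or a longitude/latitude
#' projection for 3D (spherical) coordinates.
#'
#' @param x A `"splash"` fit.
#' @param coefficient Column (index or name) of `coef(x)` to display.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.splash <- function(x, coefficient = 1L, ...) {
  val <- x$coef[, coefficient]
  cols <- grDevices::hcl.colors(64, "viridis")[
    cut(val, breaks = 64, labels = FALSE, include.lowest = TRUE)]
  if (ncol(x$coords) == 3L) {
    lon <- atan2(x$coords[, 2], x$coords[, 1])
    lat <- asin(x$coords[, 3] / sqrt(rowSums(x$coords^2)))
    graphics::plot(lon, lat, col = cols, pch = 16, cex = 0.6,
                   xlab = "longitude", ylab = "latitude", ...)
  } else {
    graphics::plot(x$coords[, 1], x$coords[, 2], col = cols, pch = 16,
                   cex = 0.6, xlab = "x", ylab = "y", ...)
  }
  invisible(x)
}
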