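# Vertex-wise (massively univariate) GLM fitting.

#' Fit the vertex-wise GLM
#'
#' Ordinary least squares of each location's time series on the task design
#' (plus nuisance block if present): `beta_v = (X'X)^{-1} X' y_v`. Nuisance
#' coefficients are estimated jointly but only task coefficients are
#' returned.
#'
#' @param Y `T x V` matrix of BOLD time series (columns = locations).
#' @param design An `"fmri_design"` from [build_design()], or a plain task
#'   design matrix.
#' @return List with `beta` (`V x KB` task coefficients), `residuals`
#'   (`T x V`), `sigma2` (length-`V` residual variances, denominator
#'   `T - #regressors`), `df_residual`, and `XtX_inv` for the task block.
#' @export
fit_vertex_glm <- function(Y, design) {
  Y <- as.matrix(Y)
  if (inherits(design, "fmri_design")) {
    X <- design$X
    full <- if (is.null(design$nuisance)) X else cbind(X, design$nuisance)
  } else {
    X <- full <- as.matrix(design)
  }
  T_vol <- nrow(Y)
  if (nrow(full) != T_vol) stopf("Y and design have different numbers of rows")
  kb <- ncol(X)
  qrX <- qr(full)
  if (qrX$rank < ncol(full)) {
    bad <- colnames(full)[qrX$pivot[(qrX$rank + 1L):ncol(full)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(bad %||% "(unnamed)", collapse = ", "))
  }
  coefs <- qr.coef(qrX, Y)                 # (KB+J) x V
  res <- Y - full %*% coefs
  dfres <- T_vol - ncol(full)
  list(beta = t(coefs[seq_len(kb), , drop = FALSE]),
       residuals = res,
       sigma2 = colSums(res^2) / dfres,
       df_residual = dfres,
       XtX_inv = chol2inv(chol(crossprod(X))))
}
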