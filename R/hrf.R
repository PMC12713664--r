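# Hemodynamic response bases and GLM design construction.
#
# The task design matrix has T rows (volumes) and K*B task columns, one per
# (condition k, temporal basis l) pair in k-major order, each obtained by
# convolving the condition's boxcar stimulus function with a basis function of
# the HRF expansion h_k(t) = sum_l beta_kl b_l(t). Nuisance columns (drift,
# motion, ...) are carried separately and never counted in the K*B task block.

#' Canonical double-gamma hemodynamic response function
#'
#' Evaluates the standard two-gamma-density HRF: a positive gamma bump with
#' mode at `peak` seconds minus an undershoot gamma bump with mode at
#' `undershoot` seconds, weighted by `ratio`.
#'
#' @param t Numeric vector of times in seconds, non-negative and ascending.
#' @param peak Delay of the response peak (seconds); mode of the first gamma.
#' @param undershoot Delay of the undershoot (seconds); mode of the second gamma.
#' @param dispersion,u_dispersion Dispersions (scale parameters, seconds) of the
#'   response and undershoot gammas.
#' @param ratio Relative amplitude of the undershoot.
#' @param normalize If `TRUE` (default), scale so the maximum over `t` is 1.
#' @return Numeric vector `h(t)`; `h(0) = 0`.
#' @examples
#' t <- seq(0, 32, by = 0.1)
#' h <- canonical_hrf(t)
#' t[which.max(h)] # about 5 s
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 1 / 6, normalize = TRUE) {
  pars <- c(peak = peak, undershoot = undershoot, dispersion = dispersion,
            u_dispersion = u_dispersion, ratio = ratio)
  if (!all(is.finite(pars)) || any(pars[1:4] <= 0) || ratio < 0)
    stopf("invalid canonical HRF parameters: %s",
          paste(names(pars), signif(pars, 4), sep = "=", collapse = ", "))
  if (any(t < 0)) stopf("HRF evaluation times must be non-negative")
  if (is.unsorted(t)) stopf("HRF evaluation times must be ascending")
  # gamma density with mode at `peak` and scale `dispersion`:
  # shape a = peak/dispersion + 1 would put the mode at `peak`; the standard
  # parameterization uses shape = peak/dispersion, rate = 1/dispersion, whose
  # mode is peak - dispersion (= 5 s with defaults).
  h <- stats::dgamma(t, shape = peak / dispersion, rate = 1 / dispersion) -
    ratio * stats::dgamma(t, shape = undershoot / u_dispersion,
                          rate = 1 / u_dispersion)
  if (normalize && length(h) && max(h) > 0) h <- h / max(h)
  h
}

#' Build a temporal HRF basis set
#'
#' Constructs a matrix of HRF basis functions sampled on a fine grid of
#' spacing `TR/16` over `[0, window]`.
#'
#' * `canonical`: the single double-gamma HRF (`B` must be 1).
#' * `fir`: `B` indicator bins tiling `[0, window)` disjointly.
#' * `bspline`: `B` B-spline columns forming a partition of unity.
#'
#' @param kind One of `"canonical"`, `"fir"`, `"bspline"`.
#' @param B Number of basis functions (>= 1).
#' @param TR Repetition time in seconds.
#' @param window Temporal support of the HRF in seconds.
#' @param ... Passed to [canonical_hrf()] for `kind = "canonical"`.
#' @return An object of class `"hrf_basis"`: list with `kind`, `B`, `TR`,
#'   `window`, `grid` (sample times) and `values` (grid x B matrix).
#' @export
hrf_basis <- function(kind = c("canonical", "fir", "bspline"), B = 1L,
                      TR = 1, window = 32, ...) {
  kind <- match.arg(kind)
  B <- as.integer(B)
  if (B < 1L) stopf("B must be >= 1")
  if (window <= 0 || TR <= 0) stopf("TR and window must be positive")
  if (kind == "canonical" && B != 1L)
    stopf("canonical basis has a single function; got B = %d", B)
  dt <- TR / 16
  grid <- seq(0, window, by = dt)
  values <- switch(kind,
    canonical = matrix(canonical_hrf(grid, ...), ncol = 1L),
    fir = {
      edges <- seq(0, window, length.out = B + 1L)
      bin <- pmin(findInterval(grid, edges, rightmost.closed = FALSE), B)
      # right-open bins: the grid point at `window` falls outside [0, window)
      v <- matrix(0, length(grid), B)
      inside <- grid < window
      v[cbind(which(inside), bin[inside])] <- 1
      v
    },
    bspline = {
      deg <- min(3L, B - 1L)
      if (deg == 0L) matrix(1, length(grid), 1L)
      else splines::bs(grid, df = B, degree = deg, intercept = TRUE)[, , drop = FALSE]
    }
  )
  values <- unname(as.matrix(values))
  assert_finite(values, "HRF basis values")
  structure(list(kind = kind, B = B, TR = TR, window = window,
                 grid = grid, values = values),
            class = "hrf_basis")
}

#' Stimulus train for one task condition
#'
#' @param onsets Event onset times in seconds (ascending, non-negative).
#' @param durations Event durations in seconds (recycled to length of onsets);
#'   a zero duration denotes a unit impulse.
#' @param amplitude Event amplitudes (recycled).
#' @param condition Condition label.
#' @return Object of class `"stim_train"`.
#' @export
stim_train <- function(onsets, durations = 0, amplitude = 1, condition = "task") {
  onsets <- as.numeric(onsets)
  if (length(onsets)) {
    if (any(onsets < 0)) stopf("onsets must be non-negative")
    if (is.unsorted(onsets)) stopf("onsets must be sorted ascending")
  }
  durations <- rep_len(as.numeric(durations), length(onsets))
  amplitude <- rep_len(as.numeric(amplitude), length(onsets))
  if (any(durations < 0)) stopf("durations must be non-negative")
  structure(list(condition = as.character(condition), onsets = onsets,
                 durations = durations, amplitude = amplitude),
            class = "stim_train")
}

#' Convolve a stimulus train with one HRF basis column
#'
#' Internally the stimulus is laid out on a fine grid (spacing `TR/16`,
#' matching [hrf_basis()]), convolved discretely with the sampled basis
#' function, and read off at the volume acquisition times `0, TR, ...,
#' (T-1)*TR`. Events with zero duration contribute unit impulses (mass
#' `amplitude`), events with positive duration boxcars of height `amplitude`.
#'
#' @param stim A [stim_train()].
#' @param basis An `"hrf_basis"` object.
#' @param column Which basis column to use.
#' @param T_vol Number of volumes.
#' @param TR Repetition time (seconds); defaults to the basis TR.
#' @return Numeric vector of length `T_vol`.
#' @export
convolve_regressor <- function(stim, basis, column = 1L, T_vol, TR = basis$TR) {
  stopifnot(inherits(stim, "stim_train"), inherits(basis, "hrf_basis"))
  if (length(stim$onsets) == 0L) return(numeric(T_vol))
  run_len <- T_vol * TR
  if (any(stim$onsets + stim$durations > run_len))
    stopf("condition '%s': events extend past the run (%.1f s)",
          stim$condition, run_len)
  dt <- TR / 16
  b <- basis$values[, column]
  if (abs(basis$grid[2] - basis$grid[1] - dt) > 1e-12) {
    # resample the basis onto the TR/16 grid
    g <- seq(0, basis$window, by = dt)
    b <- stats::approx(basis$grid, b, xout = g, rule = 2)$y
  }
  n_fine <- ceiling(((T_vol - 1L) * TR + basis$window) / dt) + 2L
  s <- numeric(n_fine)
  for (e in seq_along(stim$onsets)) {
    i0 <- round(stim$onsets[e] / dt) + 1L
    if (stim$durations[e] > 0) {
      i1 <- min(i0 + max(1L, round(stim$durations[e] / dt)) - 1L, n_fine)
      s[i0:i1] <- s[i0:i1] + stim$amplitude[e]
    } else {
      s[i0] <- s[i0] + stim$amplitude[e] / dt  # unit mass impulse
    }
  }
  x <- dt * stats::convolve(s, rev(b), type = "open")[seq_len(n_fine)]
  x[round((0:(T_vol - 1L)) * TR / dt) + 1L]
}

#' Build the GLM design matrix from stimulus timing
#'
#' Produces the `T x (K*B)` task design: columns ordered condition-major then
#' basis, each the convolution of the condition's stimulus function with a
#' basis column. Optional nuisance regressors are kept in a separate block.
#'
#' @param stims List of [stim_train()] objects (one per condition).
#' @param basis An `"hrf_basis"`.
#' @param T_vol Number of volumes.
#' @param TR Repetition time (seconds).
#' @param nuisance Optional `T x J` matrix of nuisance regressors.
#' @return Object of class `"fmri_design"`: list with `X` (task block),
#'   `nuisance`, `labels` (data.frame condition/basis), `TR`, `T_vol`,
#'   `full_rank` flag.
#' @export
build_design <- function(stims, basis, T_vol, TR = basis$TR, nuisance = NULL) {
  if (inherits(stims, "stim_train")) stims <- list(stims)
  K <- length(stims)
  if (K < 1L) stopf("need at least one condition")
  B <- basis$B
  if (T_vol <= K * B)
    stopf("T (%d) must exceed the number of task regressors K*B (%d)",
          T_vol, K * B)
  X <- matrix(0, T_vol, K * B)
  labels <- data.frame(condition = character(K * B), basis = integer(K * B),
                       stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    for (l in seq_len(B)) {
      j <- (k - 1L) * B + l
      X[, j] <- convolve_regressor(stims[[k]], basis, l, T_vol, TR)
      labels$condition[j] <- stims[[k]]$condition
      labels$basis[j] <- l
    }
  }
  colnames(X) <- paste0(labels$condition, "_b", labels$basis)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != T_vol) stopf("nuisance must have T rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuis", seq_len(ncol(nuisance)))
  }
  full <- if (is.null(nuisance)) X else cbind(X, nuisance)
  full_rank <- qr(full)$rank == ncol(full)
  if (!full_rank)
    warnf("design matrix is rank deficient (collinear regressors)")
  structure(list(X = X, nuisance = nuisance, labels = labels,
                 TR = TR, T_vol = T_vol, K = K, B = B, full_rank = full_rank),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat(sprintf("fMRI GLM design: T = %d volumes (TR = %g s), %d condition(s) x %d basis = %d task column(s), %d nuisance\n",
              x$T_vol, x$TR, x$K, x$B, ncol(x$X),
              if (is.null(x$nuisance)) 0L else ncol(x$nuisance)))
  if (!x$full_rank) cat("  ** rank deficient **\n")
  invisible(x)
}

#' Read FSL-style 3-column stimulus timing
#'
#' Tab-separated columns: onset, duration, amplitude (seconds).
#'
#' @param path File path.
#' @param condition Condition label for the returned train.
#' @return A [stim_train()].
#' @export
read_stimulus_tsv <- function(path, condition = sub("\\.[^.]*$", "", basename(path))) {
  tab <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(tab) < 2L) stopf("stimulus file %s needs >= 2 columns", path)
  if (ncol(tab) == 2L) tab$V3 <- 1
  o <- order(tab[[1]])
  stim_train(tab[[1]][o], tab[[2]][o], tab[[3]][o], condition = condition)
}

#' Export a design matrix as TSV
#'
#' Writes the task block plus nuisance columns with a header of column labels.
#'
#' @param design An `"fmri_design"`.
#' @param path Output path.
#' @export
write_design_tsv <- function(design, path) {
  full <- if (is.null(design$nuisance)) design$X else cbind(design$X, design$nuisance)
  data.table::fwrite(as.data.frame(full), path, sep = "\t")
  invisible(path)
}
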