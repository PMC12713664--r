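# Synthetic spherical-surface simulation harness and evaluation metrics.
#
# The generator emulates a group task-fMRI study on a parcellated spherical
# cortical surface: smooth [0, 1]-scaled truth fields mu_k(v), per-subject
# activation beta_{i,k}(v) = mu_k(v) + gamma_{i,k} with a scalar subject
# random effect gamma_{i,k} ~ N(0, sigma_g^2), canonical-HRF block design,
# and iid temporal noise with subject variances drawn uniformly from a
# configured range. All randomness flows from a single master seed through
# named substreams (geometry, truth, subjects, noise).

#' Quasi-uniform parcellated spherical mesh
#'
#' Vertices from a Fibonacci lattice on a sphere; parcels are Voronoi cells
#' of seeded centers refined by a few Lloyd (spherical k-means) iterations.
#' Deterministic given the seed.
#'
#' @param n_vertices Number of vertices.
#' @param n_parcels Number of parcels (<= n_vertices).
#' @param seed Integer seed (substream of the study master seed).
#' @param radius Sphere radius; default 100 to mimic cortical-surface
#'   registration spheres, so bandwidths in mm are on a realistic scale.
#' @return List with `coords` (`V x 3`), `parcels` (factor of length `V`),
#'   `radius`.
#' @export
make_sphere_mesh <- function(n_vertices, n_parcels, seed = 1L, radius = 100) {
  if (n_parcels > n_vertices) stopf("n_parcels exceeds n_vertices")
  i <- seq_len(n_vertices) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_vertices
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n_vertices) - 1)
  coords <- radius * cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  set.seed(substream_seed(seed, "geometry"))
  centers <- coords[sample.int(n_vertices, n_parcels), , drop = FALSE]
  assign <- integer(n_vertices)
  for (it in 1:10) {
    # nearest center by Euclidean distance (equivalent to geodesic on a sphere)
    cp <- coords %*% t(centers)
    assign_new <- max.col(cp, ties.method = "first")
    if (identical(assign_new, assign)) break
    assign <- assign_new
    for (k in seq_len(n_parcels)) {
      m <- colMeans(coords[assign == k, , drop = FALSE])
      if (all(is.finite(m)) && sum(m^2) > 0)
        centers[k, ] <- radius * m / sqrt(sum(m^2))
    }
  }
  list(coords = coords,
       parcels = factor(sprintf("p%03d", assign)),
       radius = radius)
}

#' Smooth compact-support truth fields
#'
#' Per condition, a sum of plateau-topped cosine-tapered spherical caps
#' ("blobs") at random vertex centers: each cap is flat over the inner
#' `plateau` fraction of its angular radius and rolls off smoothly to zero at
#' the edge, giving coherent activation patches with soft boundaries. The
#' field is max-scaled to 1 and exactly zero outside the blob supports. At
#' least one blob is small (roughly parcel-sized) and one large, so detection
#' must handle both focal and diffuse activation. The active mask is
#' `mu > 0`.
#'
#' @param geometry From [make_sphere_mesh()].
#' @param K Number of task conditions.
#' @param n_blobs Blobs per condition (>= 1).
#' @param blob_scale Multiplier on the blob angular radii.
#' @param plateau Fraction of each blob radius that is flat-topped (default
#'   0.5).
#' @param seed Integer seed.
#' @return List with `mu` (`V x K` in `[0, 1]`) and `active` (`V x K`
#'   logical).
#' @export
make_truth_field <- function(geometry, K = 2L, n_blobs = 3L, blob_scale = 1,
                             plateau = 0.5, seed = 1L) {
  if (n_blobs < 1L) stopf("need at least one blob")
  coords <- geometry$coords
  R <- geometry$radius
  V <- nrow(coords)
  set.seed(substream_seed(seed, "truth"))
  P <- nlevels(geometry$parcels)
  ang_parcel <- sqrt(4 * pi / P)        # angular scale of one parcel
  mu <- matrix(0, V, K)
  for (k in seq_len(K)) {
    centers <- coords[sample.int(V, n_blobs), , drop = FALSE]
    # one small (parcel-scale), one large, remainder in between
    radii <- blob_scale * ang_parcel *
      c(0.45, 1.4, stats::runif(max(0L, n_blobs - 2L), 0.6, 1.1))[seq_len(n_blobs)]
    amps <- stats::runif(n_blobs, 0.5, 1)
    f <- numeric(V)
    for (b in seq_len(n_blobs)) {
      cosang <- pmin(1, pmax(-1, coords %*% centers[b, ] / R^2))
      ang <- acos(cosang)
      core <- plateau * radii[b]
      inside <- ang < radii[b]
      u <- pmax(0, (ang[inside] - core) / (radii[b] - core))
      f[inside] <- f[inside] + amps[b] * 0.5 * (1 + cos(pi * u))
    }
    if (max(f) > 0) f <- f / max(f)
    mu[, k] <- f
  }
  list(mu = mu, active = mu > 0)
}

#' Block stimulus trains for the simulation design
#'
#' Alternating-block design: condition k occupies block slot k of a cycle of
#' `2K` slots of `block` seconds each (task blocks interleaved with rest), so
#' conditions never overlap.
#'
#' @param K Number of conditions.
#' @param T_vol Volumes.
#' @param TR Repetition time (s).
#' @param block Block length (s); default 15.
#' @return List of [stim_train()]s.
#' @export
make_block_stimuli <- function(K, T_vol, TR = 1, block = 15) {
  run <- T_vol * TR
  # short runs: shrink blocks so every condition fits at least one full cycle
  block <- min(block, run / (2 * K))
  cycle <- 2 * K * block
  lapply(seq_len(K), function(k) {
    onsets <- seq((2 * (k - 1)) * block, run - block, by = cycle)
    stim_train(onsets, durations = block, condition = sprintf("task%d", k))
  })
}

#' Simulate a group task-fMRI dataset
#'
#' @param geometry From [make_sphere_mesh()].
#' @param truth From [make_truth_field()].
#' @param N Subjects.
#' @param T_vol Volumes per run.
#' @param TR Repetition time (s).
#' @param sigma_g2 Between-subject variance of the scalar random effect
#'   gamma_{i,k} (High SNR: 1; Moderate: 3; Low: 5).
#' @param sigma_i2_range Range from which subject noise variances are drawn
#'   uniformly (default `c(1, 5)`).
#' @param seed Integer seed.
#' @param basis HRF basis (default canonical).
#' @return Object of class `"splash_sim"`: `geometry`, `truth`,
#'   `subject_beta` (`N x V x K` array), `Y` (list of `T x V` matrices),
#'   `design` (`"fmri_design"`), `sigma_i2`, `gamma` (`N x K`), `config`.
#' @export
simulate_subjects <- function(geometry, truth, N = 30L, T_vol = 200L, TR = 1,
                              sigma_g2 = 1, sigma_i2_range = c(1, 5),
                              seed = 1L, basis = hrf_basis("canonical", TR = TR)) {
  if (sigma_g2 < 0) stopf("sigma_g2 must be >= 0")
  if (any(sigma_i2_range <= 0)) stopf("noise variance range must be positive")
  V <- nrow(geometry$coords)
  K <- ncol(truth$mu)
  stims <- make_block_stimuli(K, T_vol, TR)
  design <- build_design(stims, basis, T_vol, TR)
  X <- design$X
  set.seed(substream_seed(seed, "subjects"))
  gamma <- matrix(stats::rnorm(N * K, 0, sqrt(sigma_g2)), N, K)
  sigma_i2 <- stats::runif(N, sigma_i2_range[1], sigma_i2_range[2])
  set.seed(substream_seed(seed, "noise"))
  subject_beta <- array(0, c(N, V, K))
  Y <- vector("list", N)
  for (i in seq_len(N)) {
    beta_i <- truth$mu + matrix(gamma[i, ], V, K, byrow = TRUE)
    subject_beta[i, , ] <- beta_i
    Y[[i]] <- X %*% t(beta_i) +
      matrix(stats::rnorm(T_vol * V, 0, sqrt(sigma_i2[i])), T_vol, V)
  }
  structure(list(geometry = geometry, truth = truth,
                 subject_beta = subject_beta, Y = Y, design = design,
                 gamma = gamma, sigma_i2 = sigma_i2,
                 config = list(N = N, T_vol = T_vol, TR = TR, K = K,
                               sigma_g2 = sigma_g2,
                               sigma_i2_range = sigma_i2_range, seed = seed)),
            class = "splash_sim")
}

#' One-call study dataset
#'
#' Convenience wrapper chaining [make_sphere_mesh()], [make_truth_field()]
#' and [simulate_subjects()], with the desk-scale defaults (`V = 2000`,
#' `P = 20`, `N = 30`, `K = 2`, `T = 200`, `TR = 1`).
#'
#' @param n_vertices,n_parcels,N,K,T_vol,TR,sigma_g2,sigma_i2_range,n_blobs,blob_scale
#'   Study configuration; see the component generators.
#' @param seed Master seed; all substreams derive from it.
#' @return A `"splash_sim"` object.
#' @export
simulate_study <- function(n_vertices = 2000L, n_parcels = 20L, N = 30L,
                           K = 2L, T_vol = 200L, TR = 1, sigma_g2 = 1,
                           sigma_i2_range = c(1, 5), n_blobs = 3L,
                           blob_scale = 1, seed = 1L) {
  geom <- make_sphere_mesh(n_vertices, n_parcels, seed = seed)
  truth <- make_truth_field(geom, K = K, n_blobs = n_blobs,
                            blob_scale = blob_scale, seed = seed)
  simulate_subjects(geom, truth, N = N, T_vol = T_vol, TR = TR,
                    sigma_g2 = sigma_g2, sigma_i2_range = sigma_i2_range,
                    seed = seed)
}

#' @export
print.splash_sim <- function(x, ...) {
  cat(sprintf("synthetic surface study: V = %d vertices, %d parcels, N = %d subjects, K = %d conditions, T = %d (TR = %g s), sigma_g^2 = %g\n",
              nrow(x$geometry$coords), nlevels(x$geometry$parcels),
              x$config$N, x$config$K, x$config$T_vol, x$config$TR,
              x$config$sigma_g2))
  invisible(x)
}

#' Estimation and detection metrics against simulation truth
#'
#' * MSE: mean over locations (and conditions) of squared estimation error.
#' * FPR: detected among truly inactive / number inactive.
#' * FNR: missed among truly active / number active.
#' * AUC: probability that a random active location out-scores a random
#'   inactive one (rank/Wilcoxon formula, ties mid-ranked).
#'
#' @param estimate `V x K` estimated field (or vector for one condition).
#' @param truth_mu `V x K` true field.
#' @param detected Logical `V x K` (or vector) detection mask; optional.
#' @param scores Numeric `V x K` ranking scores (e.g., |t|); optional,
#'   needed for AUC.
#' @param active Logical truth mask; default `truth_mu > 0`.
#' @return Data frame, one row per condition plus an `overall` row, columns
#'   `condition`, `mse`, `fpr`, `fnr`, `auc` (NA where undefined, e.g., no
#'   active or no inactive locations).
#' @export
evaluate_maps <- function(estimate, truth_mu, detected = NULL, scores = NULL,
                          active = NULL) {
  estimate <- as.matrix(estimate); truth_mu <- as.matrix(truth_mu)
  if (!all(dim(estimate) == dim(truth_mu))) stopf("shape mismatch")
  K <- ncol(truth_mu)
  active <- if (is.null(active)) truth_mu > 0 else as.matrix(active)
  one <- function(k) {
    a <- active[, k]
    mse <- mean((estimate[, k] - truth_mu[, k])^2)
    fpr <- fnr <- auc <- NA_real_
    if (!is.null(detected)) {
      det <- as.matrix(detected)[, k]
      if (any(!a)) fpr <- sum(det & !a) / sum(!a)
      if (any(a)) fnr <- sum(!det & a) / sum(a)
    }
    if (!is.null(scores) && any(a) && any(!a)) {
      sc <- as.matrix(scores)[, k]
      rk <- rank(sc)
      auc <- (sum(rk[a]) - sum(a) * (sum(a) + 1) / 2) / (sum(a) * sum(!a))
    }
    c(mse = mse, fpr = fpr, fnr = fnr, auc = auc)
  }
  per_k <- t(vapply(seq_len(K), one, numeric(4)))
  out <- data.frame(condition = c(sprintf("task%d", seq_len(K)), "overall"),
                    rbind(per_k, colMeans(per_k)))
  out$mse[K + 1L] <- mean((estimate - truth_mu)^2)
  rownames(out) <- NULL
  out
}

#' Run the full simulation study
#'
#' End-to-end pipeline: simulate (or take) a dataset, fit each requested
#' method per subject, run group inference, and score against the truth.
#' Optional parameter sweeps refit GKS across bandwidths and the
#' spline model across basis dimensions.
#'
#' Estimation error is reported two ways: `mse` is the mean over subjects of
#' the per-subject MSE against the subject-specific truth `beta_i = mu +
#' gamma_i` (the estimator's spatial accuracy), and `mse_group` is the MSE of
#' the subject-averaged map against `mu`, which additionally carries the
#' between-subject sampling floor `sigma_g^2 / N`.
#'
#' @param sim A `"splash_sim"`, or `NULL` to generate one from `...`.
#' @param methods Subset of `"glm"`, `"gks"`, `"agks"`, `"splash"`.
#' @param fwhm GKS kernel FWHM (mm); default 6 (bandwidth 2.55).
#' @param h_grid Bandwidth grid for AGKS and the GKS sweep.
#' @param M_grid Basis-dimension grid for BIC selection and the sweep.
#' @param sweep If `TRUE`, additionally evaluate GKS at every `h_grid` value
#'   and the spline fit at every fixed `M_grid` value.
#' @param estimator Spline-model estimator (default `"ols"`; the generator's
#'   temporal noise is white).
#' @param alpha_parcel,alpha_voxel Inference levels (defaults 0.1 / 0.5).
#' @param seed Master seed used when `sim` is `NULL`.
#' @param ... Passed to [simulate_study()] when `sim` is `NULL`.
#' @return List with `results` (tidy data frame: method, parameter, snr,
#'   condition, mse, mse_group, fpr, fnr, auc) and `roc` (vertex scores and
#'   truth for ROC construction, `overall` rows excluded).
#' @export
run_study <- function(sim = NULL, methods = c("glm", "gks", "agks", "splash"),
                      fwhm = 6, h_grid = NULL, M_grid = NULL, sweep = FALSE,
                      estimator = "ols", alpha_parcel = 0.1, alpha_voxel = 0.5,
                      seed = 1L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(sim)) sim <- simulate_study(seed = seed, ...)
  geom <- sim$geometry
  coords <- geom$coords
  parcels <- geom$parcels
  design <- sim$design
  N <- sim$config$N; K <- sim$config$K
  V <- nrow(coords)
  truth <- sim$truth
  snr <- sim$config$sigma_g2

  # mean spacing -> default grids on a physical scale
  if (is.null(h_grid)) {
    spacing <- sqrt(4 * pi * geom$radius^2 / V)
    h_grid <- signif(spacing * c(0.25, 0.5, 1, 1.5, 2.5), 3)
  }

  subject_beta_hat <- function(fit_fun) {
    # N x V x K array of per-subject coefficient maps
    out <- array(NA_real_, c(N, V, K))
    for (i in seq_len(N)) out[i, , ] <- fit_fun(sim$Y[[i]])
    out
  }
  res <- list(); roc <- list()
  score_method <- function(bh, method, parameter, two_stage) {
    group_mean <- apply(bh, c(2L, 3L), mean)
    mse_subj_k <- vapply(seq_len(K), function(k) mean(vapply(seq_len(N),
      function(i) mean((bh[i, , k] - sim$subject_beta[i, , k])^2),
      numeric(1))), numeric(1))
    mse_subj <- c(mse_subj_k, mean(mse_subj_k))
    detected <- matrix(FALSE, V, K)
    scores <- matrix(0, V, K)
    for (k in seq_len(K)) {
      scores[, k] <- abs(col_t_test(bh[, , k])$t)   # ROC ranks by group |t|
      if (two_stage) {
        inf <- splash_inference(bh[, , k], parcels, alpha_parcel, alpha_voxel)
        detected[inf$discoveries, k] <- TRUE
      } else {
        detected[, k] <- flat_bh_inference(bh[, , k], alpha = alpha_voxel)$discovered
      }
    }
    for (k in seq_len(K))
      roc[[length(roc) + 1L]] <<- data.frame(
        method = method, parameter = parameter,
        condition = sprintf("task%d", k),
        score = scores[, k], active = truth$active[, k])
    ev <- evaluate_maps(group_mean, truth$mu, detected, scores, truth$active)
    ev$mse_group <- ev$mse
    ev$mse <- mse_subj
    data.frame(method = method, parameter = parameter, snr = snr, ev,
               row.names = NULL)
  }

  if ("glm" %in% methods) {
    bh <- subject_beta_hat(function(Y) fit_vertex_glm(Y, design)$beta)
    res[[length(res) + 1L]] <- score_method(bh, "glm", NA_real_, FALSE)
  }
  if ("gks" %in% methods) {
    W <- gks_weights(coords, fwhm_to_bandwidth(fwhm))
    bh <- subject_beta_hat(function(Y) fit_vertex_glm(gks_smooth(Y, W), design)$beta)
    res[[length(res) + 1L]] <- score_method(bh, "gks", fwhm_to_bandwidth(fwhm), FALSE)
  }
  if ("agks" %in% methods) {
    sel <- agks_select_bandwidth(sim$Y, design, coords, parcels, h_grid)
    # smooth per selected-bandwidth group of parcels
    bh <- array(NA_real_, c(N, V, K))
    for (h in unique(sel$h)) {
      W <- gks_weights(coords, h)
      idx <- which(parcels %in% names(sel$h)[sel$h == h])
      for (i in seq_len(N)) {
        sm <- fit_vertex_glm(gks_smooth(sim$Y[[i]], W), design)$beta
        bh[i, idx, ] <- sm[idx, ]
      }
    }
    res[[length(res) + 1L]] <- score_method(bh, "agks", NA_real_, FALSE)
  }
  if ("splash" %in% methods) {
    Msel <- select_basis_dim(sim$Y, coords, parcels, design,
                             estimator = estimator, M_grid = M_grid)
    bh <- subject_beta_hat(function(Y)
      coef(splash(Y, coords, parcels, design, estimator = estimator,
                  M = Msel$M, keep_data = FALSE)))
    res[[length(res) + 1L]] <- score_method(bh, "splash", NA_real_, TRUE)
  }

  if (isTRUE(sweep)) {
    for (h in h_grid) {
      W <- gks_weights(coords, h)
      bh <- subject_beta_hat(function(Y)
        fit_vertex_glm(gks_smooth(Y, W), design)$beta)
      res[[length(res) + 1L]] <- score_method(bh, "gks_sweep", h, FALSE)
    }
    Ms <- M_grid %||% default_M_grid(max(table(parcels)), ncol(coords) + 1L)
    for (m in Ms) {
      bh <- subject_beta_hat(function(Y)
        coef(splash(Y, coords, parcels, design, estimator = estimator,
                    M = m, keep_data = FALSE)))
      res[[length(res) + 1L]] <- score_method(bh, "splash_sweep", m, TRUE)
    }
  }
  list(results = do.call(rbind, res),
       roc = if (length(roc)) do.call(rbind, roc) else NULL)
}
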