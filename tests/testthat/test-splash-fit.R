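test_that("noiseless in-span data are reconstructed exactly", {
  xy <- rand_geom(20, 2L, seed = 2)
  b <- tps_basis(xy, 6)
  des <- tiny_design(T_vol = 30L)
  set.seed(5)
  gamma0 <- rnorm(6)
  beta0 <- drop(b$S %*% gamma0)
  Y <- des$X %*% rbind(beta0)
  fit <- fit_splash_parcel(Y, des$X, b, estimator = "ols")
  expect_equal(drop(fit$beta_sp), beta0, tolerance = 1e-9)
  expect_equal(drop(fit$gamma), gamma0, tolerance = 1e-9)
})

test_that("at M = V the spline fit degenerates to the vertex GLM", {
  xy <- rand_geom(12, 2L, seed = 6)
  b <- tps_basis(xy, 12)
  des <- tiny_design(T_vol = 25L)
  set.seed(11)
  Y <- des$X %*% matrix(rnorm(12), 1) + matrix(rnorm(25 * 12), 25)
  fit <- fit_splash_parcel(Y, des$X, b, estimator = "ols")
  glm <- fit_vertex_glm(Y, des$X)
  expect_equal(fit$beta_sp, glm$beta, tolerance = 1e-10)
})

test_that("at M = d + 1 the fit is the best affine field", {
  xy <- rand_geom(25, 2L, seed = 13)
  b <- tps_basis(xy, 3)
  des <- tiny_design(T_vol = 30L)
  set.seed(14)
  beta0 <- rnorm(25)
  Y <- des$X %*% rbind(beta0) + 0.1 * matrix(rnorm(30 * 25), 30)
  fit <- fit_splash_parcel(Y, des$X, b, estimator = "ols")
  # oracle: affine regression of the vertex-GLM field on [1, x, y]
  bhat <- fit_vertex_glm(Y, des$X)$beta[, 1]
  aff <- lm.fit(cbind(1, xy), bhat)
  expect_equal(drop(fit$beta_sp), unname(fitted(aff)), tolerance = 1e-8)
})

test_that("structured FGLS equals dense GLS on materialized A = Z P Phi", {
  des <- tiny_design(T_vol = 20L, block = 5)
  X <- des$X
  for (rep in 1:20) {
    set.seed(700 + rep)
    xy <- matrix(runif(24), 12, 2)
    b <- tps_basis(xy, 4)
    phi <- matrix(runif(12, -0.6, 0.6), 1)
    s2 <- runif(12, 0.5, 3)
    beta0 <- drop(b$S %*% rnorm(4))
    Y <- X %*% rbind(beta0) + matrix(rnorm(20 * 12), 20)
    fit <- fit_splash_parcel(Y, X, b, estimator = "fgls",
                             noise = list(phi = phi, sigma2 = s2))
    oracle <- dense_splash_oracle(Y, X, b$S, phi, s2)
    expect_lt(max(abs(as.vector(fit$gamma) - oracle$gamma)), 1e-8)
  }
})

test_that("FGLS with white working noise reduces to OLS", {
  xy <- rand_geom(15, 2L, seed = 20)
  b <- tps_basis(xy, 5)
  des <- tiny_design(T_vol = 30L)
  set.seed(21)
  Y <- des$X %*% rbind(rnorm(15)) + matrix(rnorm(30 * 15), 30)
  ols <- fit_splash_parcel(Y, des$X, b, estimator = "ols")
  fg <- fit_splash_parcel(Y, des$X, b, estimator = "fgls",
                          noise = list(phi = matrix(0, 1, 15),
                                       sigma2 = rep(1, 15)))
  expect_equal(fg$gamma, ols$gamma, tolerance = 1e-8)
})

test_that("FGLS bias shrinks as independent replicates accumulate", {
  des <- tiny_design(T_vol = 30L, block = 6)
  xy <- rand_geom(10, 2L, seed = 30)
  b <- tps_basis(xy, 4)
  gamma0 <- c(1, -0.5, 0.3, 0.2)
  beta0 <- drop(b$S %*% gamma0)
  mean_err <- vapply(c(10L, 100L, 1000L), function(N) {
    set.seed(4000 + N)
    gs <- replicate(N, {
      E <- matrix(as.numeric(arima.sim(list(ar = 0.4), n = 30 * 10)), 30)
      Y <- des$X %*% rbind(beta0) + E
      as.vector(fit_splash_parcel(Y, des$X, b, estimator = "fgls")$gamma)
    })
    sqrt(sum((rowMeans(gs) - gamma0)^2))
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
})

test_that("BIC matches a hand computation and penalizes dimension", {
  # one location, three observations, one regressor
  X <- matrix(c(1, 2, 3))
  y <- matrix(c(1.1, 1.9, 3.2))
  b1 <- structure(list(S = matrix(1), M = 1L, null_dim = 1L,
                       coords = matrix(0)), class = "tps_basis")
  fit <- fit_splash_parcel(y, X, b1, estimator = "ols")
  bhat <- sum(X * y) / sum(X^2)
  rss <- sum((y - X * bhat)^2)
  n <- 3
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  expect_equal(bic_score(fit), -2 * ll + 1 * log(n), tolerance = 1e-10)

  # on in-span truth the smallest containing M wins the nested comparison
  xy <- rand_geom(40, 2L, seed = 50)
  des <- tiny_design(T_vol = 40L)
  full <- tps_basis(xy, 40)
  gamma0 <- rnorm(8, sd = 2)
  beta0 <- drop(full$S[, 1:8] %*% gamma0)
  hits <- 0L
  for (rep in 1:10) {
    set.seed(60 + rep)
    Y <- des$X %*% rbind(beta0) + 0.2 * matrix(rnorm(40 * 40), 40)
    bics <- vapply(c(4, 8, 16, 32), function(m)
      bic_score(fit_splash_parcel(Y, des$X, tps_basis(xy, m), "ols")),
      numeric(1))
    if (which.min(bics) == 2L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("basis-dimension selection pools BIC across subjects", {
  xy <- rand_geom(30, 2L, seed = 70)
  parcels <- factor(rep("p1", 30))
  des <- tiny_design(T_vol = 40L)
  full <- tps_basis(xy, 30)
  beta0 <- drop(full$S[, 1:6] %*% c(2, -1, 1, 0.5, -0.5, 1))
  set.seed(71)
  Ys <- lapply(1:4, function(i)
    des$X %*% rbind(beta0) + 0.3 * matrix(rnorm(40 * 30), 40))
  sel <- select_basis_dim(Ys, xy, parcels, des, M_grid = c(4, 6, 12, 24))
  expect_true(sel$M[["p1"]] %in% c(6L, 12L))
  # grid of one element returns that element
  one <- select_basis_dim(Ys[1], xy, parcels, des, M_grid = 8)
  expect_equal(unname(one$M), 8L)
  # single subject reduces to the per-subject argmin
  s1 <- select_basis_dim(Ys[1], xy, parcels, des, M_grid = c(4, 6, 12))
  bics <- vapply(c(4, 6, 12), function(m)
    bic_score(fit_splash_parcel(Ys[[1]], des$X, tps_basis(xy, m), "ols")),
    numeric(1))
  expect_equal(unname(s1$M), c(4L, 6L, 12L)[which.min(bics)])
  expect_error(select_basis_dim(Ys, xy, parcels, des, M_grid = integer(0)),
               "empty")
})

test_that("the splash object carries coherent coefficients and methods", {
  sim <- simulate_study(n_vertices = 200, n_parcels = 4, N = 2, T_vol = 80,
                        seed = 3)
  fit <- splash(sim$Y[[1]], sim$geometry$coords, sim$geometry$parcels,
                sim$design, M = 10)
  expect_s3_class(fit, "splash")
  expect_equal(dim(coef(fit)), c(200L, 2L))
  expect_equal(dim(coef(fit, smoothed = FALSE)), c(200L, 2L))
  expect_true(all(is.finite(fit$se)))
  # beta_sp rows equal S gamma per parcel
  p1 <- levels(sim$geometry$parcels)[1]
  idx <- which(sim$geometry$parcels == p1)
  pf <- fit$parcel_fits[[p1]]
  expect_equal(coef(fit)[idx, ], pf$beta_sp, ignore_attr = TRUE)
  # fitted + residuals reconstruct the data
  expect_equal(fitted(fit) + residuals(fit), fit$Y, tolerance = 1e-10)
  expect_output(print(fit), "SPLASH fit")
  expect_output(print(summary(fit)), "parcel summary")
  # degenerate small parcel falls back to the vertex GLM
  labs <- as.character(sim$geometry$parcels)
  labs[1:2] <- "tiny"
  fit2 <- splash(sim$Y[[1]], sim$geometry$coords, factor(labs), sim$design,
                 M = 10)
  expect_identical(fit2$parcel_fits[["tiny"]]$flag, "glm_fallback")
  expect_equal(coef(fit2)[1:2, ],
               fit2$vertex_beta[1:2, ], ignore_attr = TRUE)
})

test_that("nuisance regressors are projected out before spline fitting", {
  xy <- rand_geom(25, 2L, seed = 80)
  parcels <- factor(rep("p1", 25))
  T_vol <- 60L
  basis <- hrf_basis("canonical", TR = 1)
  stims <- list(stim_train(c(5, 35), 10, condition = "A"))
  nuis <- cbind(1, seq_len(T_vol) / T_vol)
  des <- build_design(stims, basis, T_vol, nuisance = nuis)
  set.seed(81)
  beta0 <- rnorm(25)
  drift <- nuis %*% matrix(rnorm(2 * 25, sd = 3), 2)
  Y <- des$X %*% rbind(beta0) + drift + 0.1 * matrix(rnorm(T_vol * 25), T_vol)
  fit_with <- splash(Y, xy, parcels, des, M = 25)
  # heavy drift is absorbed: smoothed estimates stay near the truth
  expect_lt(mean((coef(fit_with)[, 1] - beta0)^2), 0.01)
})
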