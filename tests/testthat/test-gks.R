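test_that("kernel weights are normalized, symmetric, and delta-like as h -> 0", {
  xy <- rand_geom(30, 2L, seed = 1)
  W <- gks_weights(xy, h = 2)
  expect_equal(as.numeric(Matrix::rowSums(W)), rep(1, 30))
  # tiny bandwidth: essentially a delta at each vertex
  W0 <- gks_weights(xy, h = 1e-6)
  expect_equal(as.numeric(Matrix::diag(W0)), rep(1, 30), tolerance = 1e-10)
  # two equidistant neighbors get equal weight
  tri <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  w <- kernel_weights(tri, v = 1, h = 1)
  expect_equal(w[2], w[3])
  expect_equal(sum(w), 1)
  # isolated vertex keeps all its weight
  iso <- rbind(c(0, 0), c(100, 100))
  wi <- kernel_weights(iso, v = 1, h = 1)
  expect_equal(wi, c(1, 0))
})

test_that("smoothing matches the brute-force double loop and is a contraction", {
  xy <- rand_geom(20, 2L, seed = 2)
  W <- gks_weights(xy, h = 3)
  set.seed(3)
  Y <- matrix(rnorm(10 * 20), 10)
  sm <- gks_smooth(Y, W)
  Wd <- as.matrix(W)
  oracle <- matrix(0, 10, 20)
  for (v in 1:20) for (u in 1:20) oracle[, v] <- oracle[, v] + Wd[v, u] * Y[, u]
  expect_equal(sm, oracle, tolerance = 1e-12)
  # constant-in-space input is reproduced exactly
  Yc <- matrix(rep(rnorm(10), 20), 10)
  expect_equal(gks_smooth(Yc, W), Yc, tolerance = 1e-12)
  expect_lte(norm(sm, "F"), norm(Y, "F"))
})

test_that("closed-form bias: zero for constant fields, pulled down across a step", {
  xy <- cbind(seq(0, 9), 0)
  W <- gks_weights(xy, h = 1.5)
  expect_equal(gks_bias(W, rep(3.7, 10)), matrix(0, 10, 1), tolerance = 1e-12)
  step <- as.numeric(xy[, 1] >= 5)
  bias <- drop(gks_bias(W, step))
  expect_lt(bias[6], 0)   # high side adjacent to the step
  expect_gt(bias[5], 0)   # low side
})

test_that("Monte-Carlo GKS means and variances match the Propositions' forms", {
  xy <- rand_geom(25, 2L, seed = 4)
  W <- gks_weights(xy, h = 2.5)
  des <- tiny_design(T_vol = 30L)
  set.seed(44)
  beta0 <- rnorm(25)
  mu <- des$X %*% rbind(beta0)
  sigma <- 1.3
  reps <- 500L
  bh <- matrix(0, reps, 25)
  for (r in seq_len(reps)) {
    Ys <- gks_smooth(mu + matrix(rnorm(30 * 25, 0, sigma), 30), W)
    bh[r, ] <- fit_vertex_glm(Ys, des$X)$beta[, 1]
  }
  expected <- drop(as.matrix(W %*% beta0))
  se <- apply(bh, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(bh) - expected) < 4 * se))
  # Prop 2: smoothed residual variation is strictly below unsmoothed
  att <- attenuation_factor(W)
  expect_true(all(att < 1))
  expect_true(all(att > 0))
})

test_that("attenuation factor has its closed-form special cases", {
  expect_equal(attenuation_factor(Matrix::Diagonal(5)), rep(1, 5))
  m <- 8
  U <- Matrix::Matrix(1 / m, m, m)
  expect_equal(attenuation_factor(U), rep(1 / m, m))
})

test_that("FWHM conversion uses the Gaussian 2 sqrt(2 log 2) factor", {
  expect_equal(bandwidth_to_fwhm(1), 2 * sqrt(2 * log(2)))
  expect_equal(fwhm_to_bandwidth(bandwidth_to_fwhm(2.55)), 2.55)
})

test_that("adaptive bandwidth selection favors wider kernels for smoother truth", {
  xy <- rand_geom(60, 2L, seed = 5)
  parcels <- factor(rep("p1", 60))
  des <- tiny_design(T_vol = 40L)
  h_grid <- c(0.5, 1.5, 3, 6)
  sel_h <- function(beta0, seed) {
    set.seed(seed)
    Ys <- lapply(1:3, function(i)
      des$X %*% rbind(beta0) + matrix(rnorm(40 * 60, 0, 2), 40))
    agks_select_bandwidth(Ys, des, xy, parcels, h_grid)$h[[1]]
  }
  smooth_truth <- 0.5 + 0.3 * xy[, 1]              # gently varying
  set.seed(55); rough_truth <- rnorm(60)           # vertex-scale variation
  hs <- vapply(1:5, function(s) sel_h(smooth_truth, 500 + s), numeric(1))
  hr <- vapply(1:5, function(s) sel_h(rough_truth, 500 + s), numeric(1))
  expect_gte(median(hs), median(hr))
  # grid of one returns that bandwidth
  one <- agks_select_bandwidth(list(des$X %*% rbind(smooth_truth)), des, xy,
                               parcels, h_grid = 2)
  expect_equal(unname(one$h), 2)
  expect_error(agks_select_bandwidth(list(), des, xy, parcels, numeric(0)),
               "empty")
})
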