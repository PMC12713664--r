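test_that("sphere mesh is on-radius, fully parcellated, and deterministic", {
  g <- make_sphere_mesh(500, 10, seed = 3)
  expect_equal(sqrt(rowSums(g$coords^2)), rep(g$radius, 500), tolerance = 1e-10)
  expect_equal(length(g$parcels), 500L)
  expect_true(all(table(g$parcels) > 0))
  expect_equal(nlevels(g$parcels), 10L)
  g2 <- make_sphere_mesh(500, 10, seed = 3)
  expect_identical(g, g2)
  expect_false(identical(g$parcels, make_sphere_mesh(500, 10, seed = 4)$parcels))
})

test_that("truth fields are [0,1]-scaled, compactly supported, and smooth", {
  g <- make_sphere_mesh(1500, 15, seed = 5)
  tr <- make_truth_field(g, K = 2, seed = 5)
  for (k in 1:2) {
    expect_equal(min(tr$mu[, k]), 0)
    expect_equal(max(tr$mu[, k]), 1)
    expect_gt(mean(tr$mu[, k] == 0), 0.2)   # compact support leaves nulls
    expect_identical(tr$active[, k], tr$mu[, k] > 0)
  }
  # smoothness: within the largest parcel, a rich spline basis captures the
  # field to < 5% relative residual
  big <- names(which.max(table(g$parcels)))
  idx <- which(g$parcels == big)
  b <- tps_basis(g$coords[idx, ], M = min(64L, length(idx)))
  f <- tr$mu[idx, 1]
  if (sum(f^2) > 0) {
    res <- f - b$S %*% crossprod(b$S, f)
    expect_lt(sqrt(sum(res^2) / sum(f^2)), 0.05)
  }
})

test_that("subject generation follows the hierarchical model", {
  g <- make_sphere_mesh(50, 4, seed = 6)
  tr <- make_truth_field(g, K = 2, seed = 6)
  # sigma_g^2 = 0: all subjects share the truth exactly
  s0 <- simulate_subjects(g, tr, N = 3, T_vol = 40, sigma_g2 = 0, seed = 6)
  for (i in 1:3) expect_equal(s0$subject_beta[i, , ], tr$mu)
  # subject random effects have the configured variance (law of large numbers)
  s1 <- simulate_subjects(g, tr, N = 2000, T_vol = 20, sigma_g2 = 1, seed = 7)
  expect_equal(var(s1$gamma[, 1]), 1, tolerance = 0.05)
  expect_true(all(s1$sigma_i2 >= 1 & s1$sigma_i2 <= 5))
  # identical config + seed reproduces the dataset bit for bit
  a <- simulate_subjects(g, tr, N = 3, T_vol = 30, seed = 9)
  b <- simulate_subjects(g, tr, N = 3, T_vol = 30, seed = 9)
  expect_identical(a$Y, b$Y)
  expect_identical(a$subject_beta, b$subject_beta)
})

test_that("evaluation metrics hit their closed-form anchors", {
  V <- 2000L
  set.seed(10)
  mu <- cbind(c(rep(0.8, 300), rep(0, V - 300)))
  perfect <- evaluate_maps(mu, mu, detected = mu > 0, scores = mu)
  expect_equal(perfect$mse, c(0, 0))
  expect_equal(perfect$fpr, c(0, 0))
  expect_equal(perfect$fnr, c(0, 0))
  expect_equal(perfect$auc, c(1, 1))
  zero <- evaluate_maps(mu * 0, mu)
  expect_equal(zero$mse[1], mean(mu^2))
  rnd <- evaluate_maps(mu * 0, mu, scores = cbind(runif(V)))
  expect_lt(abs(rnd$auc[1] - 0.5), 0.05)
  # rank-formula AUC agrees with the pROC reference
  sc <- rnorm(V) + 2 * (mu[, 1] > 0)
  ours <- evaluate_maps(mu * 0, mu, scores = cbind(sc))$auc[1]
  ref <- as.numeric(pROC::auc(pROC::roc(response = mu[, 1] > 0, predictor = sc,
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("the full study pipeline runs all methods end to end", {
  sim <- simulate_study(n_vertices = 500, n_parcels = 10, N = 8, T_vol = 120,
                        seed = 2)
  st <- run_study(sim, methods = c("glm", "gks", "agks", "splash"),
                  h_grid = c(5, 10, 20), M_grid = c(6, 12, 24))
  expect_setequal(unique(st$results$method), c("glm", "gks", "agks", "splash"))
  expect_true(all(c("mse", "mse_group", "fpr", "fnr", "auc") %in%
                  colnames(st$results)))
  ov <- st$results[st$results$condition == "overall", ]
  expect_true(all(is.finite(ov$mse)))
  # spline smoothing beats the raw GLM on subject-level accuracy
  expect_lt(ov$mse[ov$method == "splash"], ov$mse[ov$method == "glm"])
  expect_false(is.null(st$roc))
})

test_that("group error grows with between-subject variance", {
  med_mse <- vapply(c(1, 3, 5), function(sg2) {
    mses <- vapply(1:3, function(s) {
      sim <- simulate_study(n_vertices = 200, n_parcels = 4, N = 10,
                            T_vol = 80, sigma_g2 = sg2, seed = 100 + s)
      st <- run_study(sim, methods = "splash", M_grid = c(6, 12))
      st$results$mse_group[st$results$condition == "overall"]
    }, numeric(1))
    median(mses)
  }, numeric(1))
  expect_true(all(diff(med_mse) > 0))
})
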