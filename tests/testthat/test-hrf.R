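test_that("canonical HRF has the textbook shape", {
  expect_equal(canonical_hrf(0), 0)
  t <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(t)
  expect_equal(max(h), 1)
  peak <- t[which.max(h)]
  expect_gt(peak, 4.5)
  expect_lt(peak, 5.5)
  expect_true(all(is.finite(h)))
  # late undershoot dips below zero
  expect_lt(min(h[t > 10]), 0)
  expect_error(canonical_hrf(t, peak = -2), "invalid")
  expect_error(canonical_hrf(c(3, 1)), "ascending")
})

test_that("HRF basis sets satisfy their structural contracts", {
  fir <- hrf_basis("fir", B = 4L, TR = 1, window = 16)
  # four indicator columns, each supported on 4 s, tiling [0, 16) disjointly
  expect_equal(ncol(fir$values), 4L)
  widths <- colSums(fir$values) * (fir$grid[2] - fir$grid[1])
  expect_equal(unname(widths), rep(4, 4), tolerance = 0.05)
  inside <- fir$grid < 16
  expect_true(all(rowSums(fir$values[inside, ]) == 1))
  expect_true(all(rowSums(fir$values) <= 1))

  bs <- hrf_basis("bspline", B = 5L, TR = 1, window = 20)
  interior <- which(bs$grid > 1 & bs$grid < 19)
  expect_equal(rowSums(bs$values[interior, ]), rep(1, length(interior)),
               tolerance = 1e-8)

  can <- hrf_basis("canonical", TR = 0.8)
  expect_equal(drop(can$values), canonical_hrf(can$grid))
  expect_error(hrf_basis("canonical", B = 2L), "single")
})

test_that("regressor convolution matches a brute-force discrete convolution", {
  TR <- 2; T_vol <- 30L
  basis <- hrf_basis("canonical", TR = TR)
  stim <- stim_train(onsets = c(6, 30), durations = c(4, 4))
  x <- convolve_regressor(stim, basis, 1L, T_vol, TR)
  expect_length(x, T_vol)
  # brute force: direct Riemann-sum convolution evaluated at volume times
  dt <- TR / 16
  tt <- (0:(T_vol - 1)) * TR
  oracle <- vapply(tt, function(t0) {
    tau <- seq(0, basis$window, by = dt)
    b <- canonical_hrf(tau)
    s <- rowSums(vapply(seq_along(stim$onsets), function(e)
      as.numeric(t0 - tau >= stim$onsets[e] &
                 t0 - tau < stim$onsets[e] + stim$durations[e]), numeric(length(tau))))
    sum(b * s) * dt
  }, numeric(1))
  expect_equal(x, oracle, tolerance = 1e-6)
})

test_that("FIR regressors on integer-TR grids are exact lag sticks", {
  TR <- 1; T_vol <- 12L
  basis <- hrf_basis("fir", B = 4L, TR = TR, window = 4)
  stim <- stim_train(onsets = 3, durations = 0)  # impulse at volume 3
  for (l in 1:4) {
    x <- convolve_regressor(stim, basis, l, T_vol, TR)
    oracle <- numeric(T_vol); oracle[3 + l] <- 1  # lag l-1 after onset
    expect_equal(x, oracle)
  }
})

test_that("convolution is linear and shift-equivariant", {
  TR <- 1; T_vol <- 60L
  basis <- hrf_basis("canonical", TR = TR)
  expect_equal(convolve_regressor(stim_train(numeric(0)), basis, 1L, T_vol, TR),
               numeric(T_vol))
  one <- convolve_regressor(stim_train(5, 3), basis, 1L, T_vol, TR)
  two <- convolve_regressor(stim_train(c(5, 35), c(3, 3)), basis, 1L, T_vol, TR)
  other <- convolve_regressor(stim_train(35, 3), basis, 1L, T_vol, TR)
  expect_equal(two, one + other, tolerance = 1e-10)
  scaled <- convolve_regressor(stim_train(5, 3, amplitude = 2.5), basis, 1L,
                               T_vol, TR)
  expect_equal(scaled, 2.5 * one, tolerance = 1e-12)
  # delaying by m TRs shifts rows by m
  m <- 4L
  shifted <- convolve_regressor(stim_train(5 + m * TR, 3), basis, 1L, T_vol, TR)
  expect_equal(shifted[(m + 1):T_vol], one[1:(T_vol - m)], tolerance = 1e-10)
})

test_that("design matrix assembly orders and counts columns correctly", {
  T_vol <- 200L
  basis <- hrf_basis("canonical", TR = 1)
  stims <- list(stim_train(c(10, 60), 15, condition = "A"),
                stim_train(c(35, 85), 15, condition = "B"))
  des <- build_design(stims, basis, T_vol)
  expect_s3_class(des, "fmri_design")
  expect_equal(ncol(des$X), 2L)
  expect_equal(des$labels$condition, c("A", "B"))
  # column k equals the matching convolution
  expect_equal(des$X[, 2], convolve_regressor(stims[[2]], basis, 1L, T_vol, 1))
  # nuisance block is separate and not counted as task columns
  nuis <- cbind(intercept = 1, trend = seq_len(T_vol))
  des2 <- build_design(stims[1], basis, T_vol, nuisance = nuis)
  expect_equal(ncol(des2$X), 1L)
  expect_equal(ncol(des2$nuisance), 2L)
  # identical conditions are flagged
  expect_warning(build_design(list(stims[[1]], stims[[1]]), basis, T_vol),
                 "rank deficient")
  expect_error(build_design(stims, basis, T_vol = 2L), "exceed")
})

test_that("stimulus TSV round trip preserves the train", {
  st <- stim_train(c(0, 12.5, 40), c(2, 2, 0), c(1, 1, 0.5), condition = "press")
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(data.frame(st$onsets, st$durations, st$amplitude), f,
                     sep = "\t", col.names = FALSE)
  st2 <- read_stimulus_tsv(f, condition = "press")
  expect_equal(st2$onsets, st$onsets)
  expect_equal(st2$durations, st$durations)
  expect_equal(st2$amplitude, st$amplitude)
})
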