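# Shared fixtures and independent brute-force oracles.

# Random parcel geometry (2D or 3D points in a box).
rand_geom <- function(V, d = 2L, seed = 1L) {
  set.seed(seed)
  matrix(runif(V * d, 0, 10), V, d)
}

# Small canonical-HRF single-condition design.
tiny_design <- function(T_vol = 40L, TR = 1, K = 1L, block = 8) {
  stims <- make_block_stimuli(K, T_vol, TR, block = block)
  build_design(stims, hrf_basis("canonical", TR = TR), T_vol, TR)
}

# Dense generalized least squares on the explicitly materialized structured
# operator A = Z P Phi with block-diagonal AR covariance: the brute-force
# oracle for the Kronecker-structured solver.
dense_splash_oracle <- function(Y, X, S, phi, sigma2) {
  T_vol <- nrow(Y); V <- ncol(Y); KB <- ncol(X); M <- ncol(S)
  Z <- kronecker(diag(V), X)
  P <- matrix(0, KB * V, KB * V)
  for (v in seq_len(V)) for (kl in seq_len(KB))
    P[(v - 1) * KB + kl, (kl - 1) * V + v] <- 1
  Phi <- kronecker(diag(KB), S)
  A <- Z %*% P %*% Phi
  Sig_inv <- matrix(0, T_vol * V, T_vol * V)
  for (v in seq_len(V)) {
    Sv <- ar_covariance(phi[, v], sigma2[v], T_vol)
    idx <- (v - 1) * T_vol + seq_len(T_vol)
    Sig_inv[idx, idx] <- solve(Sv)
  }
  yvec <- as.vector(Y)
  gamma <- solve(t(A) %*% Sig_inv %*% A, t(A) %*% Sig_inv %*% yvec)
  list(gamma = gamma, A = A)
}

# Literal Benjamini-Hochberg step-up, written independently of bh_select.
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * alpha / m)
  if (!length(pass)) return(integer(0))
  sort(o[seq_len(max(pass))])
}

# Simulate one group replicate at the coefficient level: mixed null /
# partially active parcels, subject maps beta_i = mu + noise (SD tau).
coef_level_group <- function(P = 20L, Vp = 100L, N = 30L, frac_active_parcels = 0.25,
                             frac_active_vertices = 0.3, effect = 0.5, tau = 1) {
  V <- P * Vp
  parcels <- factor(rep(sprintf("p%02d", seq_len(P)), each = Vp))
  mu <- numeric(V)
  act_parcels <- seq_len(round(frac_active_parcels * P))
  for (p in act_parcels) {
    idx <- (p - 1L) * Vp + seq_len(round(frac_active_vertices * Vp))
    mu[idx] <- effect
  }
  beta <- matrix(rnorm(N * V, 0, tau), N, V) + rep(mu, each = N)
  list(beta = beta, parcels = parcels, mu = mu, active = mu > 0,
       null_parcels = setdiff(seq_len(P), act_parcels))
}
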