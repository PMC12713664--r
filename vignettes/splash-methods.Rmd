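---
title: "Parcel-localized spline regression for task fMRI: model, choices, and caveats"
author: "splash package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcel-localized spline regression for task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splash)
```

# The model

Task fMRI analyses start from the massively univariate GLM: at each location
$v$ the BOLD series $y_v \in \mathbb{R}^T$ is regressed on stimulus functions
convolved with a hemodynamic response basis,
$$ y_v = X\beta_v + \varepsilon_v, \qquad X \in \mathbb{R}^{T \times KB}, $$
with one column per (condition $k$, temporal basis $l$) pair. Fitting each
location separately ignores the spatial coherence of real activation and
yields fragmented maps; smoothing the *data* with a Gaussian kernel (GKS)
fixes the fragmentation but biases both the coefficients and their variances
(see the closed-form oracles below).

This package instead smooths in *coefficient space*, within predefined
parcels. For the $V$ locations of one parcel, each coefficient field is
represented on a low-rank thin-plate regression spline basis $S \in
\mathbb{R}^{V \times M}$,
$$ (\beta_{kl1}, \dots, \beta_{klV})^\top = S\gamma_{kl}, $$
so the stacked parcel model is
$$ Y = Z P \Phi \Gamma + \varepsilon, \qquad
   Z = I_V \otimes X, \quad \Phi = I_{KB} \otimes S, $$
with $P$ the permutation from location-major to basis-major coefficient
ordering and $\Gamma \in \mathbb{R}^{KBM}$ the spline coefficients. The
temporal noise is location-specific AR($p$), block-diagonal across
locations. The estimator is feasible GLS,
$$ \hat\Gamma = (A^\top\hat\Sigma^{-1}A)^{-1}A^\top\hat\Sigma^{-1}Y,
   \qquad A = ZP\Phi, $$
computed without materializing $A$: the normal matrix accumulates as
$\sum_v (X^\top\hat\Sigma_v^{-1}X) \otimes (s_v s_v^\top)$ over locations,
where $s_v$ is row $v$ of $S$. Whitening per location uses the exact banded
Cholesky factor of the AR precision obtained from the Levinson–Durbin
recursion, at cost $O(Tp)$ per series. Under homoskedastic independent
errors the estimator reduces to OLS, and because the basis is orthonormal
the OLS solution is simply $\hat\gamma_{kl} = S^\top\hat\beta_{\cdot,kl}$
applied to the vertex-GLM coefficients — a property the test suite exploits
as an exact cross-check against a dense GLS solve on the materialized $A$.

Smoothed fields are reconstructed as $\hat\beta_{sp} = S\hat\gamma$, with
plug-in variances $s_v^\top \widehat{\mathrm{Var}}(\hat\gamma)\, s_v$. With
iid noise and truth inside the spline span, the estimator is exactly
unbiased and the variance estimator is unbiased in finite samples; both
properties are verified by Monte-Carlo in the test suite.

# The spline basis

The thin-plate regression spline basis for a parcel is built from its
coordinates alone (2D or 3D), so the same construction serves volumes and
cortical surfaces; spherical registration surfaces are handled through their
3D Euclidean embedding (chordal distances), not geodesics. The radial kernel
is $\eta(r) = r^2\log r$ in 2D and $\eta(r) = -r$ in 3D. The low-rank basis
keeps the $M - (d+1)$ eigenvectors of the kernel matrix with largest
absolute eigenvalue plus the affine polynomials $\{1, x_1, \dots, x_d\}$,
orthonormalized by sequential Gram–Schmidt with the polynomial block first.
Two consequences matter in practice:

* the affine space is always representable, so a parcel with constant or
  linear activation is fitted exactly at the minimal $M$;
* the bases are *nested* in $M$ (the $M$-basis is the first $M$ columns of
  the $V$-basis), so projection residuals are monotone in $M$ and at
  $M = V$ the fit reproduces the vertex GLM exactly.

Eigenvector signs are fixed (largest-magnitude entry positive) so the
construction is deterministic. Near-dependent candidate columns are dropped
with a $10^{-9}$ relative tolerance, which makes degenerate geometries
(collinear points, duplicated coordinates) behave gracefully. The basis is
deliberately used **unpenalized**: $M$ itself is the smoothing control.
No attempt is made to be bit-compatible with other TPRS implementations;
only the span properties above are contracted.

# Choosing M, and the AR order

$M$ is selected per parcel by BIC, $-2\hat\ell + KBM\log(TV)$, with the
Gaussian log-likelihood concentrated over the variance for OLS and evaluated
under the fitted AR noise for FGLS. Since group inference compares subjects
at a fixed spatial resolution, `select_basis_dim()` sums the BIC across
subjects and picks one $M^\ast$ per parcel for the whole group (smallest on
ties). The default candidate grid is geometric with about 8 points from
$d+2$ to $\min(V_p, 100)$. The likelihood form, $n = TV$ and $k = KBM$ are
documented package choices — standard BIC bookkeeping for this model, since
no canonical definition exists for the parcel-stacked likelihood.

The AR order defaults to $p = 1$ (configurable to 8). FGLS is one-step:
AR coefficients are estimated per location from vertex-GLM residuals by
Yule–Walker (with explicit stationarity projection of the roots, and a
degenerate-series guard), then a single GLS pass is run. Iterating
estimator and noise model is possible but unnecessary for the moderate
autocorrelations typical of fMRI noise. Parcels with fewer than $d+3$
locations cannot carry a spline basis and fall back to the vertex GLM,
flagged in the fit object.

# Kernel smoothing comparators and their oracles

For evaluation, the package carries the standard comparators. GKS smooths
the data with normalized Gaussian weights
$w_{vu} \propto \exp(-\|v-u\|^2/2h^2)$ truncated at $3h$. Two closed forms
make GKS auditable:

* **bias**: $E[\hat\beta_{GKS}(v)] = \sum_u w_{vu}\beta_u$, so the bias is
  the kernel average minus $\beta_v$ — zero only for locally constant
  fields (`gks_bias()`);
* **variance attenuation**: with iid $N(0,\sigma^2)$ noise the usual
  residual variance estimator has expectation $\sigma^2\sum_u w_{vu}^2$
  (`attenuation_factor()`), i.e., kernel smoothing *always* understates
  uncertainty, inflating downstream test statistics.

Bandwidth and FWHM are related by $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,h$
(2.55 ↔ 6). The adaptive variant (AGKS) selects $h$ per parcel by a BIC in
which the per-location residual variance is first *de-attenuated* by
$\sum_u w_{vu}^2$ (otherwise the likelihood improves spuriously with $h$)
and the parameter count is $KB \cdot V_\mathrm{eff}$ with $V_\mathrm{eff} =
\sum_v \sum_u w_{vu}^2$, which equals $V$ with no smoothing and shrinks as
neighborhoods pool. This BIC is a package definition: the de-attenuation
uses the variance oracle above, and $V_\mathrm{eff}$ is the natural
effective-parameter count for a row-stochastic smoother. Selection is per
parcel by default.

# Two-stage selective inference

Group inference is hierarchical. Stage 1 screens parcels: per subject the
parcel-average coefficient is computed, and the one-sample $t$ across $N$
subjects enters a BH pass at $\alpha_\mathrm{parcel}$ (default 0.1),
yielding the selected set $\mathcal{S}$. Stage 2 tests vertices only within
selected parcels, with BH at the *selection-adjusted* level
$$ q_p = \alpha_\mathrm{voxel}\,\frac{|\mathcal{S}|}{P}, $$
which controls the expected average FDR over the selected parcels at
$\alpha_\mathrm{voxel}$ (default 0.5); the average is defined as 0 when
nothing is selected. The default levels follow the convention of a liberal
parcel screen with strict within-parcel control. Tests are two-sided by
default; all comparator pipelines use flat vertex-wise BH at
$\alpha_\mathrm{voxel}$ so that detection comparisons are level-matched.
Inference runs one (condition, basis) coefficient at a time; how to combine
discoveries across multiple temporal basis functions is left to the user.

# The synthetic surface harness

`simulate_study()` emulates a group study on a quasi-uniform sphere
(Fibonacci lattice, radius 100 to match cortical registration spheres, so
bandwidths are in familiar mm units) with Voronoi/Lloyd parcels. Truth
fields are sums of plateau-topped, cosine-tapered spherical caps, max-scaled
to $[0,1]$ and exactly zero outside their supports (the active mask is
$\mu > 0$ — a package definition, since compact support makes "active"
unambiguous). At least one cap is parcel-sized and one larger, so detection
faces both focal and diffuse signal. Subjects share the truth up to a scalar
random effect $\gamma_{i,k} \sim N(0, \sigma_g^2)$ per condition, constant
over space; SNR regimes are $\sigma_g^2 = 1$ (high), 3, 5 (low). Time
series use a canonical-HRF alternating block design (15 s blocks,
shortened automatically for brief runs) with iid temporal noise whose
subject variances are uniform on $[1,5]$. All randomness flows from one
master seed through named substreams, so identical configurations reproduce
bit-for-bit. Defaults are desk-scale: $V = 2000$, $P = 20$, $N = 30$,
$K = 2$, $T = 200$, TR 1 s; $T$ is a package choice (any value with
$T \gg KB$ behaves equivalently for block designs).

What the generator does **not** emulate: drift, motion, physiological
artifacts, spatially correlated noise, inter-subject misregistration, or
HRF variability. Passing tests therefore certify the estimator's algebra,
its sampling properties under its own assumptions, and the relative
behavior of methods — not performance on real cortical data.

Two estimation-error summaries are reported by `run_study()`. `mse` is the
mean over subjects of the per-subject MSE against the subject-specific truth
$\mu + \gamma_i$: the spatial accuracy of the estimator itself. `mse_group`
is the MSE of the subject-averaged map against $\mu$; because the random
effect is a single scalar per subject and condition, this carries an
irreducible floor of $\sigma_g^2/N$ (0.033 at high SNR with $N = 30$) that
no estimator can remove, and comparisons between methods are dominated by
that common term. The headline accuracy comparisons therefore use `mse`.

A caveat on desk-scale comparisons with kernel smoothing: at $V = 2000$ the
mean vertex spacing is ≈ 8 mm, so a 2.55 mm kernel (FWHM 6) averages almost
nothing and GKS nearly coincides with the raw GLM, while parcels have only
≈ 100 vertices, so the spline fit's variance-reduction factor
$M^\ast/V_p$ is larger than it would be with several-hundred-vertex
parcels on a full-resolution mesh. Relative-MSE ratios between the spline
fit and kernel smoothing at desk scale are therefore conservative
(pessimistic for the spline model) compared to full-resolution meshes.
The robustness comparison sweeps bandwidths from below the vertex spacing
up to blob scale — the under- to over-smoothing range in which kernel
choice genuinely matters — against spline dimensions from 5 to 48.

# Numerical choices and problem sizes

* All linear solves go through QR or Cholesky; the structured normal matrix
  is Cholesky-factored and a failure raises an error naming the parcel.
* Whitening uses exact increasing-order predictors for the first $p$
  samples, so the whitened covariance is the identity to machine precision
  (asserted against dense Toeplitz algebra in the tests).
* BH ties are resolved by sorted order; BIC and bandwidth ties take the
  smaller (more regularized) candidate.
* Duplicated coordinates are collapsed before the eigendecomposition with a
  warning; the basis still returns one row per input location.
* The bundled validation runs use: 1000 Monte-Carlo replicates for the
  unbiasedness/variance checks (30-vertex parcel), 2000 for the kernel
  oracles, 500 group replicates for the selective-FDR study (20 parcels of
  100 vertices, $N = 30$), the full desk-scale study ($V = 2000$) for the
  accuracy comparison, and 5 seeded repetitions of a reduced study
  ($V = 600$, $P = 10$, $N = 16$) for the smoothing-parameter sweep. These
  sizes are the package's chosen trade-off between Monte-Carlo error and
  turnaround.

# Known limitations

* Chordal (not geodesic) distances on surfaces; for parcel-sized
  neighborhoods the difference is small, but long-range smoothing across
  deep folds is not modeled.
* Noise is independent across locations (block-diagonal $\Sigma$); spatially
  correlated noise would require a different whitening strategy.
* The selective guarantee is on the *average* FDR over selected parcels,
  not per-parcel.
* GIFTI support covers ASCII-encoded arrays only; binary GIFTI should be
  converted upstream. NIfTI volumes are supported through the RNifti
  adapter.
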