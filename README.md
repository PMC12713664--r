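# splash

Spatially adaptive activation mapping for task-based fMRI.

Vertex-wise GLM analyses of task fMRI produce fragmented, noisy activation
maps because each location is fitted independently; smoothing the BOLD data
with a Gaussian kernel (the standard remedy) blurs activation boundaries,
biases the coefficient estimates toward their neighborhood average, and
provably understates their variances. `splash` implements the alternative of
smoothing in **coefficient space, within brain parcels**: inside each parcel
the activation field of the hemodynamic GLM

&nbsp;&nbsp;&nbsp;&nbsp;*y<sub>v</sub> = Xβ<sub>v</sub> + ε<sub>v</sub>*,&nbsp;&nbsp;
*X ∈ ℝ<sup>T×KB</sup>* (HRF-convolved stimulus regressors)

is represented on a low-rank thin-plate regression spline basis *S ∈
ℝ<sup>V×M</sup>*, *(β<sub>kl1</sub> … β<sub>klV</sub>)<sup>⊤</sup> =
Sγ<sub>kl</sub>*, and the stacked parcel model

&nbsp;&nbsp;&nbsp;&nbsp;*Y = ZPΦΓ + ε*,&nbsp;&nbsp;
*Z = I<sub>V</sub> ⊗ X*, *Φ = I<sub>KB</sub> ⊗ S*

is fitted by structured OLS or feasible GLS with location-specific AR(p)
noise (Levinson–Durbin banded whitening; the operator *A = ZPΦ* is never
materialized). The spatial resolution *M* is selected per parcel by BIC,
shared across subjects. Group inference is a two-stage selective procedure:
Benjamini–Hochberg screening of parcel-level t-statistics at
α<sub>parcel</sub>, then vertex-level BH within each selected parcel at the
adjusted level *q<sub>p</sub> = α<sub>voxel</sub>·|S|/P*, which controls the
expected average FDR over the selected parcels.

The package also provides the Gaussian-kernel-smoothing comparators (fixed
and BIC-adaptive bandwidth) together with their closed-form bias and
variance-attenuation oracles, a synthetic parcellated-sphere simulation
harness, plain-text (TSV) dataset IO with NIfTI/GIFTI adapters, and a small
command line interface (`inst/cli/splash-cli.R`).

Intended users: neuroimaging statisticians and methods-oriented fMRI
researchers who want adaptive spatial smoothing with honest uncertainty and
FDR control, at vertex- or voxel-level resolution, without the cost of
fully Bayesian spatial models.

## Worked example

Simulate a small group study on a parcellated sphere, fit the model per
subject at a shared BIC-selected resolution, and run group inference:

```r
library(splash)

sim <- simulate_study(n_vertices = 800, n_parcels = 10, N = 12,
                      T_vol = 160, seed = 42)
print(sim)
#> synthetic surface study: V = 800 vertices, 10 parcels, N = 12 subjects,
#>   K = 2 conditions, T = 160 (TR = 1 s), sigma_g^2 = 1

# one spatial resolution per parcel, shared across the group
M <- select_basis_dim(sim$Y, sim$geometry$coords, sim$geometry$parcels,
                      sim$design)$M

fit <- splash(sim$Y[[1]], sim$geometry$coords, sim$geometry$parcels,
              sim$design, estimator = "fgls", M = M)
print(fit)
#> SPLASH fit (FGLS, AR(1)): 800 locations, 10 parcel(s), 2 task coefficient(s)
#>   spline dimension M: median 14 (range 5-17)
#>   total BIC: 532264.5

# stack per-subject maps for condition 1 and run group inference
beta <- t(sapply(sim$Y, function(Y)
  coef(splash(Y, sim$geometry$coords, sim$geometry$parcels, sim$design,
              M = M, keep_data = FALSE))[, 1]))
inf <- splash_inference(beta, sim$geometry$parcels)
print(inf)
#> two-stage selective FDR inference: N = 12 subjects, P = 10 parcels
#>   stage 1 (BH at 0.1): 4 parcel(s) selected
#>   stage 2 (BH at q_p = 0.2 = 0.5 * 4/10): 294 vertex discoveries

# score the group map against the simulation truth
ev <- evaluate_maps(colMeans(beta), sim$truth$mu[, 1],
                    detected = seq_len(800) %in% inf$discoveries,
                    scores = abs(flat_bh_inference(beta)$t))
print(ev[1, ], digits = 2)
#>   condition  mse fpr  fnr  auc
#> 1     task1 0.03   0 0.53 0.97
```

Reading the output: the per-parcel spline dimensions (median 14 of ~80
vertices per parcel) show how much each parcel is regularized; four of ten
parcels survive the activation screen, so vertex-level testing runs at the
selective level q<sub>p</sub> = 0.2 rather than 0.5; the group map attains
MSE 0.03 against the [0, 1]-scaled truth with no false-positive vertices,
missing mainly low-amplitude blob edges (`fnr` counts every vertex with
μ > 0, however faint, as active), and ranks active above inactive vertices
with probability 0.97 (`auc`).

`coef()`, `fitted()`, `residuals()`, `summary()` and `plot()` work on the
fitted object; `run_study()` executes the full multi-method benchmark
(GLM / GKS / adaptive GKS / spline model, with optional smoothing-parameter
sweeps) and returns tidy results tables.

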