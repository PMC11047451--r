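---
title: "Models and methods in esikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in esikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esikit)
```

`esikit` implements a desk-scale pipeline for electrophysiological source
imaging: surface geometry, analytic forward models, lead-field quality
control, cross-spectral estimation, geometric priors, regularized inverse
solvers, and a between-modality comparison of source spectra. This vignette
explains the models, the parameters that matter, the numerical choices, and
what the built-in synthetic fixtures do and do not demonstrate.

## Geometry

Surfaces are triangular meshes in SI meters (`tri_mesh`). Head-model
surfaces must be closed orientable 2-manifolds with outward orientation;
`is_closed_manifold()` checks the half-edge pairing.

**Normals and curvature.** Vertex normals are area-weighted averages of
incident face normals. Mean curvature uses the cotangent Laplace–Beltrami
operator with mixed Voronoi vertex areas; the sign convention is positive on
convex (gyral-crown-like) regions, so a sphere of radius R has curvature
1/R everywhere (the icosphere fixtures recover this to ~1e-4 relative).
The curvature prior relies on this sign convention to separate its gyral and
sulcal branches.

**Decimation.** `resample_mesh()` is an iterative edge collapse driven by
quadric error (area-weighted sum of squared distances to the original face
planes), with a lazy-deletion min-cost queue. A collapse is admitted only
when the link condition holds (the endpoints share exactly two neighbors),
which preserves closedness, orientability and genus on sphere-like meshes.
The new vertex is placed at the best of the two endpoints and the midpoint
rather than the quadric-optimal position; this keeps vertices on or near the
input surface and avoids solving small ill-conditioned systems, at the cost
of slightly higher quadric error per collapse.

**Geodesics.** Distances are shortest paths on the edge graph augmented,
for every interior edge, with a "virtual" edge connecting the two opposite
triangle vertices at their unfolded-in-plane length. Pure edge-graph
Dijkstra overestimates sphere geodesics by up to ~6–8% along directions
misaligned with the lattice; the unfolded cross-edges bring this to ~1–2%,
which is ample for interpolation weights. The interpolation operator
(`build_interpolant()`) assigns each high-resolution vertex inverse-geodesic
weights over its k = 3 nearest low-mesh vertices, normalized to sum to one;
a coincident vertex takes weight one, avoiding division by zero. Rows are
therefore stochastic and constants interpolate exactly.

**Deformed graph Laplacian.** `graph_laplacian(mesh, eps)` returns
L + εI for the combinatorial Laplacian L = D − A. The shift makes the
standardization factor an exact inverse while converging uniformly to L as
ε → 0; at ε = 0 the factor falls back to the Moore–Penrose pseudoinverse,
which annihilates the constant nullspace. Deformed Laplacians are sometimes described through a
second-order expansion around the minimum singular value; among operators
with the required uniform-convergence behavior the εI shift is the simplest,
so it is the one implemented.

## Forward models

Three analytic models are provided. The infinite-medium dipole potential is
the boundary-free baseline every quality-control comparison uses; any
positive conductivity gives the same correlations because Pearson r is
scale-free. The three-shell concentric-sphere EEG model solves, per
spherical-harmonic degree n, a 5×5 boundary-value system (continuity of
potential and normal current at the two interior interfaces, insulation at
the outer boundary) in radii nondimensionalized by the outer radius — this
keeps the system well conditioned to n = 80 and beyond. The series is
truncated at `n_terms` (default 60); the tail is O((b/R)^n) in the source
eccentricity b, i.e. ~1e-5 relative at b = 0.8·r_inner and machine-level
below b = 0.5·r_inner. The MEG model is the closed-form spherical-conductor
magnetometer field; it is independent of the conductivity profile and
exactly silent for radial dipoles, properties the tests assert at 1e-12.

Default fixture geometry: radii 0.079/0.082/0.088/0.092 m for
cortex/inner skull/outer skull/scalp and conductivities 0.33/0.0042/0.33 S/m
— conventional textbook values, configurable in the JSON config. EEG lead
fields and data are average-referenced by default (columns then sum to
zero), toggleable per call.

## Lead-field quality control

The QC index correlates a tested lead field against the homogeneous
baseline: per sensor across sources (rows) and per source across sensors
(columns). Flags are raised strictly below 0.7 for sensors and 0.33 for
sources — boundary values pass — and zero-variance rows or columns are
flagged as undefined rather than given r = 0. A global ordinary
least-squares fit of the vectorized lead fields (slope, intercept, R²)
summarizes the comparison; under additive noise at signal-to-noise ratio s
the expected R² is s/(s+1), which the tests verify at s = 10.

`qc_control_loop()` automates the correction cycle: compute lead fields and
correlations, flag, check source–inner-skull distances, and while
violations remain, warp the inner skull locally outward
(`warp_surface_outward()`: displacement along the away-from-source
direction with a quartic falloff inside a 15 mm smoothing radius, clamped
and declared incorrigible if it would cross the outer skull) and recompute.
Cases an interactive workflow would hand to a human are labeled
`incorrigible` instead of pausing; `template_fallback()` then substitutes
the packaged template model with provenance recorded. The minimum clearance
defaults to 2 mm and is configurable.

The spherical analytic models are numerically stable at any
source–surface distance, so the fixtures emulate the instability of
boundary-element solvers with `make_unstable_lf_provider()`: source columns
closer to the inner skull than a critical distance receive deterministic
additive noise growing as the clearance shrinks. This reproduces the
characteristic failure signature — distance flags coinciding with collapsed
source-wise correlations — and, after the outward warp, the recomputed lead
field is clean, so the minimum source correlation increases monotonically
across iterations. The QC fixture restricts sources to the cortical cap
beneath the 10–20 montage (z > 1 cm): on a full sphere, sources on the far
side are essentially unobservable to a 19-channel top-of-head montage and
the bounded-conductor and infinite-medium solutions decorrelate there for
physical rather than numerical reasons, which is not the situation the QC
is designed to detect (real cortices lie under the electrode array).

## Spectral estimation

Three transforms produce coefficients whose per-frequency Hermitian
covariance `S_f = (1/m) Σ z zᴴ` (no mean removal; coefficients are
zero-mean by construction) is the cross-spectral tensor:

* `fft_coefficients()` — windowed non-overlapping segments; m = number of
  segments; Hann or rectangular window normalized to unit power.
* `gfht_coefficients()` — per target frequency, the analytic signal of the
  data filtered by a frequency-domain Gaussian; m = number of time samples.
  "Bandwidth" means two standard deviations of the Gaussian (1 Hz default);
  as it shrinks the per-bin power converges to the single-bin periodogram,
  a property the tests check as a monotone discrepancy decrease over
  bandwidths 2 → 0.25 Hz.
* `bfht_coefficients()` — zero-phase brick-wall band-pass plus analytic
  signal per band; default partition delta 0.5–4, theta 4–8, alpha 8–13,
  beta 14–30, gamma 30 Hz–0.9×Nyquist, giving the default five-slice
  tensor. Frequency-domain filtering was chosen over IIR filtfilt because
  it is exactly zero-phase, deterministic, and makes the narrowband limit
  analysis exact; its ringing at band edges is immaterial for covariance
  estimation on stationary fixtures.

The default analysis grid is 0.5–50 Hz in 0.5 Hz steps — 100 frequencies,
DC excluded (a linear detrend removes it). All slices are Hermitian
positive semidefinite by construction, asserted across transforms and
random seeds.

## Priors

All priors act by standardizing the lead field before solving and
de-standardizing afterwards, so they compose with any solver:

* **Rotational invariance** (`field`): solve on the normal projection (one
  complex scalar per source), then lift with the free-orientation posterior
  — each source gets an isotropic 3-component prior with scale γ_i/3, so
  the lifted 3×3 spectral tensors are not biased by the local lead-field
  Gram matrix — and finally re-project onto each source's real
  maximum-amplitude direction (top eigenvector, sign aligned with the
  normal for determinism). On the sphere fixture a normal-aligned simulated
  source recovers its direction to well under 15 degrees.
* **Curvature depth compensation** (`curvature`): weights
  `w = intercept + slope·H` with separate gyral (H ≥ 0, boundary assigned
  to the gyral branch) and sulcal branches; columns are divided by w. The defaults
  (slope 0.5, intercept 1, both branches) are this package's own and are
  exposed in the configuration.
* **Graph Laplacian** (`laplacian`): multiply by the deformed-Laplacian
  inverse. This matters for linear solvers: on a smooth simulated patch a
  ridge minimum-norm inverse improves markedly under the standardization
  (the test shows correlation with truth rising from ~0.81 to ~0.94),
  whereas the sparse Bayesian solver adapts its per-source scales and gains
  nothing on such fixtures.
* **Parcellation** (`parcellation`): one variance scale per labeled group
  in the sparse Bayesian solver. With one label per source it reduces
  exactly to the ungrouped solver. Group-level recovery is demonstrated on
  a well-posed fixture (12 sensors, 30 sources, balanced groups); with 19
  sensors and a group spanning most of a 500-source space the group model
  is not identifiable — a limitation of the design, not of the optimizer.

Standardizations are composed curvature → Laplacian → rotational
invariance (column scalings, then smoothing, then orientation); the order
is a package choice, as none is prescribed.

## Inverse solvers

**Type one (spectra).** `sssbl_solve()` maximizes the evidence of
`v ~ CN(0, L diag(γ) Lᴴ + σ²I)` in the source scales γ with the penalty
α₁·Σ√γ + α₂·Σγ (the square-root/linear combination realizing the
quasinorm-plus-nuclear regularization on the diagonal model). Each
iteration computes posterior second moments M_i and solves the scalar
M-step exactly: the stationarity condition is the quartic
α₂u⁴ + (α₁/2)u³ + mu² − mM = 0 in u = √γ, which has a unique positive root
(one sign change) found by safeguarded Newton from u = √M. With zero
penalties this is the classic evidence (EM) update γ ← M. On convergence
the quasilinear operator is T = diag(γ)Lᴴ(L diag(γ)Lᴴ + σ²I)⁻¹ and the
source cross-spectrum is T S_vv Tᴴ plus the posterior-variance correction
on the diagonal. The support statistic is the posterior concentration
p_i = γ_i l_iᵀ Σ⁻¹ l_i ∈ [0, 1) — the fraction of the prior scale retained
by the data — thresholded at 0.95 by default; this realization of
"significantly different from zero" is a package convention. σ² defaults to
the mean of the smallest ⌈N/4⌉ eigenvalues of each slice.

**Type two (cross-spectra).** `hgridge_solve()` is the closed form: with
S = U diag(d) Uᴴ, the penalized stationary point has eigenvalues
(−d + √(d² + 4α))/(2α). `hglasso_solve()` minimizes
−logdet Θ + tr(SΘ) + α Σ_{i≠j}|Θ_ij| over Hermitian positive-definite
matrices by ADMM; the complex soft-threshold shrinks moduli and preserves
phases, and the returned sparse iterate has exact off-diagonal zeros, so
the saturation property (α ≥ max off-diagonal of S gives an exactly
diagonal precision) holds exactly. The two-step pathway applies either
penalty to the support-restricted source cross-spectrum; the one-step
pathway is an EM iteration on the sensor tensor (E-step: posterior source
cross-spectrum under the current precision; M-step: penalized graph fit)
whose penalized marginal likelihood is tracked and must not decrease five
iterations in a row. Likelihood terms are scaled by the effective sample
count m carried by the tensor.

**Baselines.** `eloreta_solve()` iterates the weight fixed point
w_i = √(l_iᵀ M l_i), M = (L W⁻¹ Lᵀ + reg·I)⁺, to 1e-8 and returns
T = W⁻¹LᵀM; with reg → 0 it attains exact localization for noiseless point
sources, verified exhaustively over all 500 fixture sources. Ties in the
power argmax break to the lowest index. `lcmv_solve()` is the unit-gain
minimum-variance beamformer row `l_iᴴC⁻¹/(l_iᴴC⁻¹l_i)`.

`apply_operator()` maps coefficients as Tz and cross-spectra as TSTᴴ with
explicit re-Hermitianization, so stored operators plus data metrics
reproduce stored source metrics without archiving the latter.

## Source-spectra comparison

Given strictly positive spectra tensors (sources × frequencies × cases)
for two modalities, `fit_scaling_model()` regresses MEG on EEG log-spectra
per frequency, pooling sources and cases: intercept a_f (scale difference),
slope b_f (exponential contraction), residuals E. The generative fixture
draws EEG log-normal and sets MEG = exp(a_f)·EEG^{b_f}·exp(noise), so the
noiseless fit is exact and at noise SD 0.1 the parameters are recovered
within ±0.02.

`permutation_max_test()` compares regression-corrected tensors cell-wise
with the mean difference standardized by the pooled unbiased standard
error, and controls the family-wise error with the permutation distribution
of the maximum absolute statistic over the whole grid: modality labels of
the 2C cases are reshuffled (whole-case permutation, respecting the
between-subject design), and a cell is significant when its
observed-included p-value (1 + #{max ≥ |t|})/(B + 1) is at or below α.
The test is applied to residuals rather than rescaled spectra; a switch is
not exposed because the residual route is the one whose null calibration
the package verifies: over 200 null Monte-Carlo replications at reduced
scale (100 sources × 5 frequencies × 15 cases per modality, 500
permutations) the family-wise rejection rate lands near the nominal 0.01.
`band_indicator_map()` marks a source in a band when any in-band frequency
is significant; the maps are monotone in the significance set.

## Fixtures: what they show and what they do not

Sources are simulated as band-limited coupled stationary Gaussian
processes, built segment-wise in the frequency domain from per-bin complex
Gaussian draws with the target cross-spectral covariance. The theoretical
tensor is therefore exact for the matching rectangular-window FFT
estimator, which is what makes sampling-rate convergence tests (error
halving when m quadruples) possible. This matches the asymptotic
complex-Gaussian regime the cross-spectral solvers assume; it does not
emulate nonstationarity, nonlinearity, 1/f backgrounds, artifacts of real
recordings, or realistic cortical folding — passing fixtures demonstrates
correctness of the estimators under their stated model, not performance on
clinical data. Recovery problem sizes (19 sensors, 500 sources, m = 200
alpha-band samples, SNR 10 dB; 10-node graphs at m = 2000) were chosen as
the smallest instances that still exhibit each method's characteristic
behavior.

The solver-recovery fixture plants its three active sources in the cortex
beneath the electrode cap, for the same observability reason given above
for the QC scene.

## Configuration, determinism, limitations

All tunables live in a JSON configuration with full defaults
(`default_config()`): missing keys fall back, unknown keys are errors.
Coordinates are SI meters (RAS); layouts that look like millimeters
(any coordinate > 1.5) are converted with a warning. Every stochastic path
takes an explicit seed, and the command-line `simulate` path is
byte-deterministic for a fixed seed.

Known limitations: no realistic boundary-element or finite-element forward
solver (external lead fields can be imported through the binary + JSON
container); spherical-cap 10–20 geometry rather than digitized positions;
the deformed Laplacian is the εI shift described above; the one-step
Hermitian-graph EM is one faithful reading of a procedure whose update
equations are not public; and the grouped (parcellation) model requires
group structure commensurate with the sensor count to be identifiable.
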