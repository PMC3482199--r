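---
title: "Motor-equivalent structure and persistence of postural sway: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-equivalent structure and persistence of postural sway: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swayucm)
```

This vignette is the package's own account of the model and the analysis
decisions behind it: what is computed, under which assumptions, which
defaults matter, and what the synthetic validation does and does not show.

## 1. The kinematic model

Quiet-standing posture is modelled as a planar chain in the sagittal plane:
six joints (ankle, knee, hip, lumbo-sacral LS, lower neck C7,
atlanto-occipital AO) connect five massive segments (shank, thigh, pelvis,
trunk, head). Angles are in degrees, positive for anterior pitch; x is
anterior, y vertical; lengths in mm.

Segment *elevation* angles (pitch from vertical) are cumulative sums of the
joint angles, so the two coordinate systems are linearly equivalent and the
whole analysis can be re-run in either (`joints_to_elevation()`,
`elevation_jacobian()`).

**Head-point convention.** "Head position" is the distal end of the
C7-to-head segment, and the head segment's mass is lumped at that point.
The AO joint rotates only massless geometry distal to it (a nominal vertex
segment used to carry the angle in marker data). This convention is forced
by the structure of the task-sensitivity table the model must reproduce:
the AO sensitivities of both positional tasks are exactly zero, which is
only possible if nothing with mass lies distal to the head point. A
consequence worth knowing: for marker data, the seven mass-bearing chain
points cannot encode the AO angle, so `synthesize_markers()` emits an
eighth point (`head_top`, 120 mm above the head point by default) and
`markers_to_angles()` reads the AO angle from it. With that point, the
marker round trip recovers all six angles to numerical precision.

**Anthropometry defaults.** Segment lengths (440, 440, 100, 450, 150 mm)
describe a ≈1.75 m adult; relative masses (0.122, 0.200, 0.142, 0.455,
0.081) follow standard segmental tables with foot mass folded into the
shank (the feet do not move in this model) and arm mass into the trunk
(arms hang at the sides), and segment CoM fractions 0.433/0.433/0.5/0.5/1.
These were fixed once, from the tables, and give positional sensitivities
at upright posture of (16.7, 9.6, 3.7, 2.6, 0.21, 0) mm/° for CoM position
and (27.6, 19.9, 12.2, 10.5, 2.6, 0) mm/° for head position — within about
15% of typical adult values. Individual anthropometry differs, so the
package treats published magnitudes as order-of-magnitude checks only; all
defaults are overridable in `build_chain()`.

**Linearization point.** The Jacobian is evaluated at the per-trial mean
joint configuration. Whether to linearize per trial or per sample is
genuinely open; the per-trial mean is the conventional choice for
quiet-stance UCM work, keeps the subspaces fixed within a trial (a
prerequisite for component-wise autocorrelation), and is what the shipped
pipeline uses. Per-sample Jacobians can be obtained by calling
`task_jacobian()` frame by frame for sensitivity analyses.

**Orientation tasks are exactly linear**: trunk orientation is the sum of
the first four joint angles, head orientation the sum of all six, with
posture-independent sensitivities (1,1,1,1,0,0) and (1,1,1,1,1,1). The
analytic positional Jacobians are verified against central finite
differences of the forward models at random postures to 1e-6 relative
tolerance in the test suite.

## 2. Preprocessing

Raw kinematics are smoothed with a zero-phase (forward–backward)
Butterworth low-pass filter, order 5, cut-off 10 Hz (`lowpass()`), the
standard choice for sway kinematics: postural fluctuations live well below
10 Hz, marker jitter well above. The bidirectional pass squares the
magnitude response (≥60 dB attenuation at 4× cut-off) and leaves constants
exact. Bilateral markers are averaged (`average_bilateral()`) before
angles are computed. Readers/writers cover CSV (angles and markers, with
the sampling rate in a header comment line) and TRC; C3D is a binary
format outside this package's text-based I/O scope — convert to TRC/CSV
upstream.

## 3. UCM decomposition

For task Jacobian `J`, `subspace_basis()` returns an orthonormal basis of
the null space (from the SVD of `J`) and the unit range vector `J/|J|`.
The SVD basis is made deterministic by a sign convention (first
non-negligible entry of each basis vector positive): any orthonormal
re-spanning leaves TEV and TRV unchanged (trace argument, asserted in
tests), but the *per-dimension* autocorrelations used later do depend on
the spanning, so a fixed basis is essential for reproducibility (§5).

`ucm_decompose()` demeans about the reference posture, projects, and
normalizes variance by subspace dimension: `TEV = mean of 5 coordinate
variances`, `TRV = variance of the range coordinate`. Variances are
population variances (divisor T); the choice cancels in the index.
Degenerate inputs (TRV = 0) yield a flagged record (`undefined = TRUE`,
`NA` index) rather than an error or an infinity, so group statistics can
exclude them explicitly (`ucm_index_stats()` counts exclusions). The index
is log-transformed with the natural log; the log base only rescales the t
statistics' inputs linearly and does not affect decisions.

## 4. The COV test

The covariation-by-randomization test asks the same question at task
level, immune to inflation by high-variance low-sensitivity joints: does
destroying cross-joint covariation increase task variance?
`make_surrogate()` permutes each joint's column independently over time —
marginals are preserved exactly, cross-joint structure dies. `cov_index()`
permutes *deviations about the trial mean* and passes surrogates through
the full nonlinear forward model (the original study's surrogate details
are not fully specified; permuting raw columns instead is exposed as an
option and is equivalent up to the mean). 100 surrogates per trial is the
default — the surrogate-mean's Monte-Carlo error is then well below the
between-subject spread — and a seed is mandatory in pipeline runs. A
block-permutation option (`block_s`) preserves within-joint
autocorrelation for users who want a dynamics-respecting null; it is not
the default because the classical test is defined on sample-wise
permutation.

## 5. Persistence

Persistence is the squared Pearson autocorrelation
`R²(τ) = cor(x(t), x(t+τ))²` at dyadic lags 1–128 s
(`lag_samples = round(lag_s × fs)`); a 300 s trial at 100 Hz leaves 172 s
of overlap at the longest lag. R² is invariant to affine rescaling, so
persistence comparisons are mathematically independent of component
amplitudes — the two halves of the analysis (amount, time) are separate
evidence. No detrending beyond the trial-mean removal already inherent in
the decomposition is applied.

TEV is 5-dimensional, so its R² is averaged over dimensions in two
schemes:

- **equal**: per null-basis coordinate, unweighted mean. This depends on
  the basis choice on anisotropic data; the fixed SVD basis makes it
  deterministic, and `tev_basis_diagnostic()` recomputes the profile in a
  randomly rotated null basis to *surface* (not hide) any basis
  dependence.
- **sensitivity**: per *joint* on the parallel component in joint
  coordinates, weighted by `J_j²/ΣJ_k²`. The weighted reading is defined
  on joints (a "task sensitivity of a null-basis coordinate" would not be
  well-defined), zero-sensitivity joints drop out exactly.

TRV is univariate in both schemes. Before t tests, R² values are mapped
by the inverse hyperbolic tangent with the definition interval rescaled to
[0, 1]: `z = atanh(2R² − 1)`, clipping R² to `[1e-6, 1 − 1e-6]` so z stays
finite; the clip only matters for essentially-zero correlations.

## 6. Statistics

Group inference uses the transform-then-t-test chain the conclusions rest
on: one-sample t tests of log indices against 0 (Holm-corrected across
the four tasks), and paired t tests of TEV-vs-TRV z values at each lag
(Holm-corrected across the eight lags). All tests are two-sided — the
directional hypothesis could justify one-sided tests, but two-sided is the
conservative default when sidedness is unstated. Omnibus repeated-measures
ANOVAs with sphericity corrections are deliberately not re-implemented;
they belong to general-purpose statistical tooling, and the package's
tables (one row per subject × task × lag) feed directly into e.g.
`stats::aov` or `afex`.

## 7. The synthetic generator: what it emulates, what it does not

`simulate_sway()` is the package's stand-in for participant recordings: a
stationary AR(1)/Ornstein–Uhlenbeck process per dimension, five along the
task's null space (coefficient `exp(-1/(tau_par·fs))`, stationary SD
`sd_par`) and one along the range direction (`tau_orth`, `sd_orth`), added
to a mean posture. AR(1) is the simplest process with the required
"accumulate vs correct" contrast; the shipped conditions are 100 Hz,
300 s, `tau_par = 30 s`, `tau_orth = 0.5 s`, `sd_par = 1.0°`,
`sd_orth = 0.3°`, 14 subjects, which place every joint's SD in the
0.1–2° range observed in quiet standing and produce the qualitative
pattern the analysis is designed to detect: log UCM and COV indices > 0
and TEV persistence above TRV persistence from 2 s lags upward.

Closed forms make the generator a parameter-recovery oracle: each
dimension's R² at lag L samples is `phi^(2L)`, amplitude and persistence
are controlled by separate knobs (`sd` vs `tau`), and symmetric settings
(`tau_par = tau_orth`, `sd_par = sd_orth`) give a null log index. The test
suite checks all three, plus stationary-SD calibration to a few percent.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data:

- Real sway is not a sum of six independent AR(1) processes; it has
  nonstationarities, drifts and spectral structure the model lacks. The
  pipeline's *correctness* is established on the model; its *conclusions*
  on real data depend on the data.
- The generative structure is bound to one coordinate system (joint
  angles) and one task's manifold. A notable consequence found during
  validation: re-analysing the simulated data in elevation-angle
  coordinates reproduces the UCM-index sign and the TEV>TRV persistence
  ordering, but **not** the COV result — destroying elevation-angle
  covariation *reduces* task variance on this generative model (the slow
  null-space patterns keep proximal partial sums small exactly where the
  elevation-space task weights are largest). Human data evidently carries
  richer per-joint fast content. The corresponding acceptance check is
  left failing rather than adjusting the generator post hoc; treat it as a
  documented model limitation and a caution that COV-by-randomization is
  coordinate-dependent.
- At long lags (comparable to `tau_par` and the trial length) sample
  autocorrelations of the slow component are dominated by sampling
  variability: only ~10 correlation times fit in a 300 s trial at
  `tau_par = 30 s`. Persistence estimates at 64–128 s are noisy for *any*
  method; the paired tests inherit honest between-subject spread there.

`simulate_cohort()` derives per-subject seeds from a base seed and can
jitter anthropometry; `synthesize_markers()` plus `add_marker_noise()`
(default 2 mm, the nominal accuracy of optical capture) exercise the
marker-level pipeline, and the noise-robustness acceptance check confirms
the UCM conclusion survives 2 mm marker noise after 10 Hz filtering.

## 8. Numerical choices and degenerate inputs

- Degrees externally, radians internally; positional sensitivities in
  mm/° (factor π/180 included).
- Orthonormality, null-ness (`J·N = 0`) and the variance partition
  `Σ var(θ_j) = 5·TEV + TRV` are asserted to 1e-9–1e-10 in tests.
- Zero Jacobians, non-positive lengths, zero-length marker segments,
  too-short series for the filter or for a lag's minimum overlap (30
  samples by default) raise errors; zero-variance series yield flagged
  `NA` R².
- Lags must be strictly increasing; `round(lag_s × fs)` defines the
  sample lag.
- Constant log samples in `one_sample_log_test()` return t = 0 (when the
  mean is already at the null) or a flagged `NA` instead of dividing by a
  zero standard error.

## 9. Problem sizes used in the shipped validation

Unit tests run on series of 10³–10⁵ samples chosen so that Monte-Carlo
bands (quoted per test) are a small multiple of the estimator's sampling
SD. The end-to-end validation uses the full shipped conditions: a
14-subject cohort of 300 s × 100 Hz trials, 100 COV surrogates per trial;
the type-I-error check uses 200 replicate 6-subject cohorts at reduced
trial length, where the null rejection rate stays within a binomial band
of the nominal 5%.
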