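---
title: "Methods: intra-condensate single-molecule tracking analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intra-condensate single-molecule tracking analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensateSPT)
```

# The problem

Biomolecular condensates formed by proteins such as FUS look homogeneous in
bulk fluorescence, but single-molecule tracking (SMT) inside them reveals
strong spatial heterogeneity: nanometer-scale regions ("nanodomains") where
protein and RNA diffusion is restricted, without any detectable change in
protein density. This package implements the quantitative machinery needed
to characterize that heterogeneity from SMT data: a trajectory classifier,
localization-density and step-size maps, edge-corrected pair-correlation
statistics of nanodomains, running-window diffusion-state segmentation, and
droplet-fusion rheology from optical-tweezers force traces. Because raw
microscopy data of this kind are rarely deposited, the package also ships a
synthetic-data generator that reproduces the statistical structure the
analysis assumes, so every stage is testable against known ground truth.

# Coordinate and sampling conventions

* Pixel size 0.117 µm; images are `(row = y, col = x)` matrices with pixel
  `i` covering `[(i-1)·px, i·px)` on histogram grids (a point exactly on an
  edge belongs to the higher bin). Rendered videos put a point at `x_um` on
  the pixel column `round(x_um / px) + 1`.
* Frame interval: 0.02 s by default. The trajectory-reconstruction regime
  this pipeline targets records 10,000 frames in 200 s, which pins 20 ms
  per frame; every function still takes `frame_interval` explicitly.
* Localization error: 16 nm per axis (`loc_error_sd = 0.016`), the static
  error measured for surface-attached molecules in this imaging regime.

# The synthetic-data generator

`simulate_trajectories()` draws, per molecule, a class (immobile, confined,
normal, or two-state switching), a geometric trajectory length
(photobleaching-like; mean 20 frames, minimum 5 localizations — the
distribution of real SMT track lengths is not published, so geometric is
the one-parameter choice consistent with a constant per-frame bleaching
hazard), and then a 2D walk:

* normal: Brownian steps with per-axis variance `2 D dt`, reflected at the
  condensate boundary;
* confined: the same inside a nanodomain disk, with hard reflection at the
  domain boundary (no confinement potential is specified by the imaging
  literature for these structures; a spring-like Ornstein--Uhlenbeck mode
  `confinement = "spring"` is available for robustness checks);
* immobile: a fixed anchor, so observed motion is pure localization noise;
* switching: alternates trapped/free with a per-frame escape probability,
  re-trapping on re-entry into a domain.

Localization noise is added independently per frame. With
`subframe_steps > 1` the walk is simulated on a finer grid and the recorded
position is the within-frame average, emulating continuous (full-frame)
camera exposure; `render_video()` can additionally rasterize each
sub-position as a Gaussian spot and average the renderings, with Poisson
photon noise and Gaussian read noise.

What the generator does *not* emulate: 3D diffusion and defocus, blinking
photophysics, background structure from neighboring condensates, and the
"lensing-effect" illumination stripes seen in some real condensates. Tests
passing on synthetic data therefore validate the estimators' correctness
and power under the stated model, not robustness to every optical artifact
of real data.

# Detection and linking

`dog_filter()` band-passes each frame with the difference of two sampled
Gaussian kernels (sigmas 1 and 3 px, radius `4 sigma`, separable, replicate
padding) — exactly equivalent to convolution with the `G1 − G3` difference
kernel, which is how the tests verify it. `detect_spots()` runs a
scale-normalized Laplacian-of-Gaussian detector at the scale implied by the
5-px object diameter (`sigma = d / (2·sqrt(2))`), takes 3×3 local maxima,
and refines them by quadratic (parabolic) sub-pixel interpolation. The
spot "quality" is defined here as the LoG response at the maximum, since
the cited tracker's exact quality metric is not published; the default
threshold is 5, and `auto_quality_threshold()` implements the data-driven
alternative (first histogram valley above the dominant false-positive
mode, falling back to 5 when the distribution is unimodal).

`link_trajectories()` performs frame-to-frame optimal bipartite assignment
on squared distance with a hard cap (5 px intra-condensate, 15 px dilute
phase), no gap closing. Births and deaths enter through the standard
block-cost construction with alternative cost `1.05 · cap²`, and the
assignment is solved exactly by a shortest-augmenting-path method (an
O(n³) Jonker–Volgenant-style solver implemented in the package and tested
against brute-force permutation enumeration; a greedy mode exists for
speed). No weighted-assignment solver was available among the installed
packages, which is why the solver is implemented here.

# Trajectory classification

For each trajectory:

1. immobile if the mean frame-to-frame step is below 30 nm (about 1.06×
   the mean step expected from 16 nm noise alone);
2. otherwise fit `log(MSD) = alpha·log(tau) + log(2 n D)` (n = 2) by
   unweighted least squares over lags `1..max(floor(N/2), 4)` — half the
   trajectory, with at least 4 MSD points for short tracks;
3. excluded if the fit's R² < 0.7 (this also catches near-immobile tracks
   whose MSD is noise-dominated);
4. confined if `alpha < 0.7`, normal otherwise (the boundary value 0.7 is
   assigned to normal).

The time-averaged MSD uses all overlapping pairs; `n_pairs` is recorded
per lag but the fits are unweighted, matching the plain least-squares
formulas of the source procedure. Two estimator properties worth knowing:

* **Negative alpha bias.** The unweighted log-log fit over half the track
  length is biased low by roughly 0.05–0.08 on pure Brownian motion
  (long-lag time-averaged MSD values are noisy, and the log transform
  converts their scatter into a downward pull). The bias shrinks when the
  fit is restricted to short lags — the test suite demonstrates this — but
  the half-length rule is the procedure being reproduced, so it is kept.
  Consequently a "mean alpha ≈ 1" check on Brownian ensembles is passed at
  0.88–1.05, not 0.95–1.05.
* **Classifier power.** Recall per class depends strongly on trajectory
  length and on the ratio of step size to localization noise. On long,
  well-separated synthetic classes the per-class recall among retained
  (non-excluded) trajectories exceeds 80%; with 16 nm noise the immobile
  threshold sits close to the noise floor, so a noticeable fraction of
  immobile molecules is excluded rather than misclassified.

For non-confined trajectories, `fit_d_sigma()` fits the camera-corrected
model `MSD(tau) = 4 D tau + 4 sigma² − 8 D R dt`, with motion-blur
coefficient `R = 1/6` for continuous full-frame exposure (the printed form
of this model elsewhere is dimensionally garbled; the per-axis standard
form `2 D tau + 2 sigma² − 4 D R dt`, doubled for two dimensions, is what
is implemented — it is the only form under which simulated continuous
exposure returns an unbiased D and an intercept-recoverable R). Negative
`D` or `sigma²` estimates are clipped at zero and flagged. For ensemble
estimates use `pooled_msd()` and fit once: averaging per-trajectory fit
results over a classified subset is selection-biased (demonstrated in the
tests), pooling is not.

`state_array_spectrum()` estimates the distribution of apparent diffusion
coefficients over a log-spaced 64-point grid (0.01–100 µm²/s): each
trajectory's sum of squared displacements is Gamma-distributed with shape
equal to its step count and scale `4 (D dt + sigma² − 2 D R dt)`, and
mixture occupations are estimated by EM with a weak symmetric Dirichlet
prior (concentration 1.01). This is a deliberate simplification of the
published variational state-array machinery — a grid likelihood with EM —
and is documented as such; it resolves single states to the nearest grid
point and 50/50 two-state mixtures to within ±0.1 mass in the tests.

# Maps, segmentation, and weighted correlation

`subsample_pool()` caps every trajectory longer than 10 steps at exactly
10 randomly chosen localizations (shorter trajectories pass whole), which
prevents single long trajectories from printing artificial puncta into the
maps. `density_map()` bins the pool on the 117-nm grid;
`stepsize_heatmap()` assigns each step's length to the pixel containing
its midpoint and stores per-pixel means plus counts.

`segment_condensates()` smooths the whole-FOV density map with a
sigma = 1 px Gaussian, thresholds at 10 localizations per pixel, discards
components under 200 px, and crops each survivor with 3-px padding.
Automatic rejection of stripe-like ("lensing") condensates is deliberately
not implemented — that step is a manual inspection in practice — but
`circularity()` provides a shape score to assist review: `4·pi·A / P²`
computed from a traced boundary polygon (area by shoelace, perimeter after
light contour smoothing, so that rasterized disks score ≈ 1 and squares
score ≈ pi/4 instead of inheriting staircase bias).

`weighted_pcc()` is the weighted Pearson coefficient with weighted means;
the conventional weight is the squared per-pixel localization count
(`pcc_weights()`), reflecting that pixels visited by more molecules are
more reliable. Whether the published weighting used one channel's counts
or both is ambiguous, so `pcc_weights()` defaults to the summed (joint)
counts squared with per-channel modes available. Pixels without data are
excluded rather than zero-filled, since a zero-filled empty pixel would
claim knowledge the data do not contain.

# Pair-correlation statistics and radial profiles

`pair_correlation()` computes `G(r) = N_interest(r) / (N_ref · rho · ring
area)` on overlapping annuli (width `dr` = 100 nm sliding in 20-nm steps,
r from 0 to 1 µm). Edge correction iterates reference points: any
reference closer to the condensate boundary than `r + dr` has its analytic
ring area `2·pi·r·dr` replaced by the in-mask annulus area, computed on an
8-fold subdivided pixel grid (`ring_area_in_mask()`; verified against
10⁶-sample Monte-Carlo to 1%). References whose annulus lies entirely
outside the mask are skipped for that r. Auto mode excludes self-pairs;
`rho` is the per-condensate density of interest particles.

`fit_exponential()` fits `G(r) = 1 + A·exp(−r/R)` with initialization
`A0 = G(first bin) − 1`, `R0 = 0.2` µm, and a small ladder of fallback
starts; perfectly flat curves return `A = 0` with `R` marked
unidentifiable instead of a spurious fit. `aggregate_and_bootstrap()`
pools per-condensate curves by particle-count-weighted averaging and
resamples condensates with replacement (5,000 rounds by default),
refitting each round; the "parametric bootstrapping" label used for this
procedure elsewhere is a nomenclature mismatch — what is described, and
implemented, is a non-parametric resampling of condensate-level curves.
The overlapping r bins are statistically correlated; the fits treat them
as independent (as the plain formulas imply) and honest uncertainty comes
from the bootstrap over condensates, not from per-bin errors.

`nanodomain_centers()` offers both published centre definitions — LoG
puncta on the condensate's density map, or centroids of
confined-classified trajectories — and `radial_profile()` normalizes
centre distances by the condensate's equivalent radius (from area,
assuming a circle) and divides each bin by its uniform-expectation ring
fraction, so complete spatial randomness is flat at 1. Bins are 0.05 in
normalized radius over [0, 1.2] (the bin grid is a package choice, exposed
as arguments); bins entirely beyond the nominal radius have zero expected
mass and are reported as `NA`.

# Running-window segmentation

`running_window_profile()` slides a 20-step window (stride 1) and reuses
the whole-trajectory MSD fitters per window. `hmm_segment()` fits a
two-state Gaussian-emission hidden Markov model on the standardized
features (alpha and log10 D_app by default; single-feature modes exist
since the published analysis does not state which features its HMM used),
with k-means initialization, 10 perturbed restarts keeping the best
likelihood, and an EM tolerance of 1e-4. States are canonicalized by mean
alpha (lower = confined), decoding is Viterbi, and a transition is
reported at the first frame of the first window in the new state.
Near-constant series short-circuit to a single state. No installed R
package provides a Gaussian HMM, so Baum–Welch/Viterbi are implemented in
the package and exercised against constructed fixtures (clean two-level
series localize transitions to ±2 windows).

# Fusion rheology

`detect_fusion_onset()` block-averages the 50-kHz force trace to 5 Hz,
takes the discrete gradient, and calls an event only if the largest
absolute gradient exceeds 5× the median absolute gradient (the no-event
threshold is a package default, exposed as an argument); the onset is then
refined within ±1 coarse block at 500 Hz resolution. `fit_fusion()` fits
`F = A + B·exp(−t/tau) + C·t` to the full-rate data over a 1-s window
after onset (window length is a package default — whether the original fit
spanned a window or the full trace is not stated), initializing `tau` from
the downsampled 1/e decay time with fallback starts. `A` absorbs the force
baseline and `C` the trap-interference drift, so `tau` is invariant to
offsets and linear drift — a property the tests assert. Manual exclusion
of non-fusing traces is replaced by explicit flags; nothing is silently
rejected. `otsu_area()` gives the companion confocal read-out (global Otsu
threshold, largest component, area in µm²).

# The random-walk control

The one quantitative benchmark computed entirely from published
information is the classifier's false-confinement rate on pure random
walks. Its simulation parameters are not published; two facts pin the
regime. First, the classifier thresholds themselves (30 nm immobile
cut-off against 16 nm noise) only exercise the immobile/confined/normal
competition when frame steps are tens of nanometers. Second, a control
simulated at the truly dilute diffusion scale (≈ 10 µm²/s) would have
frame steps hundreds of times the localization error, where the confined
label arises only from fit scatter (≈ 18% regardless of frame interval or
length distribution) and never reaches the reported ≈ 32%.
`random_walk_control()` therefore simulates the control at the
intra-condensate step scale: mean frame step ≈ 40 nm (D = 0.025 µm²/s at
20 ms), 16 nm noise, geometric lengths (mean 20, min 5), and reports the
confined share of the three retained categories — the same denominator the
published category fractions use. Under these conditions the confined
fraction is 28–32% across seeds and is insensitive to the length
distribution (mean 10–30 frames shifts it by < 5 points); both properties
are asserted in the acceptance tests.

# Problem sizes and numerical choices

The shipped tests and scripts use problem sizes chosen to make each
statistical check decisive at desk scale: 1,000–2,000 trajectories for
ensemble recoveries (pooled D to ~2%, sigma to ~5% at the intra-condensate
scale), 700 blurred trajectories for the motion-blur coefficient
(recovered within 0.03 of 1/6), 100 simulated force traces for the tau
suite, 10⁴ points for complete-spatial-randomness checks, and 30 points
for brute-force G(r) oracle comparisons. Ring areas use an 8× subdivided
grid; Monte-Carlo oracles use 10⁶ samples. Degenerate inputs (flat
curves, empty masks, constant series, single-point trajectories) return
flags or errors rather than numbers, and every stochastic routine takes an
explicit seed; identical seeds give bit-identical output.

# Known limitations

* The alpha classifier inherits the published estimator's negative bias
  and length sensitivity; category fractions should only be compared
  between conditions tracked and classified identically.
* The state-array estimator is a simplified grid-EM, not the full
  variational treatment; it is accurate for well-separated states but
  will not reproduce the original's fine regularization behavior.
* Edge-corrected G(r) assumes the mask is the true condensate boundary;
  segmentation bias propagates into `rho` and the edge areas.
* The HMM assumes two states with Gaussian emissions on windowed features;
  window-level smoothing merges switches shorter than about half a window.
* Condensate qualification reproduces the automatic rules only; the
  manual stripe-artifact rejection step has no automated counterpart here.
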