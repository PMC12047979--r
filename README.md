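# condensateSPT

Single-molecule tracking (SMT) inside biomolecular condensates shows that
"homogeneous" droplets are anything but: FUS and RNA molecules are
repeatedly caught in nanometer-scale regions — nanodomains — where their
diffusion is restricted, with no accompanying change in protein density.
`condensateSPT` is an R package for quantifying that heterogeneity. It is
aimed at single-molecule biophysicists who have (or simulate) intra-
condensate trajectory data and want the full analysis chain: detection and
linking, diffusion classification, density/step-size maps, nanodomain
spatial statistics, diffusion-state segmentation, and droplet-fusion
rheology.

## What it computes

**Trajectory classification.** Each trajectory is labeled immobile
(mean step < 30 nm), confined, or normal by the anomalous exponent of its
time-averaged MSD, fitted on log-log axes over half the trajectory length
(minimum 4 lag points):

    log(MSD) = α · log(τ) + log(2nD),    n = 2

with R² < 0.7 fits excluded and α < 0.7 defining confinement. Apparent
diffusion coefficients and localization error come from the camera-
corrected model

    MSD(τ) = 4Dτ + 4σ² − 8DRΔt,   R = 1/6 (continuous exposure)

and a state-array spectrum (gamma jump likelihood on a log-spaced D grid
with EM occupations) resolves diffusive subpopulations.

**Maps.** Localization density maps and step-size heatmaps on the 117-nm
camera grid, with oversampling suppression (≤ 10 points per trajectory),
condensate segmentation (σ = 1 smoothing, 10 locs/px threshold, ≥ 200 px),
weighted pixel-wise Pearson correlation (weights = squared localization
counts), and contour-based circularity.

**Nanodomain statistics.** Edge-corrected auto/cross pair correlation

    G(r) = N_interest(r) / (N_ref · ρ_interest · ring area)

on sliding annuli (dr = 100 nm, 20-nm steps, r ≤ 1 µm), where references
near the boundary use the in-mask annulus area; exponential clustering
fits `G(r) = 1 + A·exp(−r/R)` with condensate-level bootstrap (5,000
rounds), nanodomain centers (LoG puncta or confined-trajectory centroids),
and ring-area-normalized radial profiles.

**State transitions.** Running-window (20 steps) α and D_app series with
two-state Gaussian HMM segmentation of confined vs normal episodes.

**Fusion rheology.** Onset detection on 50-kHz dual-trap force traces
(5-Hz downsampled gradient peak) and nonlinear fits of

    F(t) = A + B·e^(−t/τ) + C·t

for the characteristic fusion time τ, plus Otsu condensate areas from
confocal frames.

A synthetic-data generator (Brownian / immobile / nanodomain-confined /
switching molecules in disk-shaped condensates, 16-nm localization error,
motion blur by sub-frame averaging, PSF-rendered videos, and exponential-
relaxation force traces) provides labeled ground truth for every stage.

## Worked example

```r
library(condensateSPT)

# one condensate with five nanodomains; mixed molecular population
nd <- data.frame(x_um = c(1.45, 2.55, 2.00, 1.60, 2.45),
                 y_um = c(2.00, 1.60, 2.70, 2.55, 2.35),
                 radius_um = 0.15, escape_prob = 0.02)
sc <- scene(center = c(2, 2), radius = 1.6, nanodomains = nd)
p  <- sim_params(n_tracks = 2000, D_free = 0.1, D_confined = 0.03,
                 p_immobile = 0.10, p_confined = 0.45, seed = 101)
tr <- simulate_trajectories(sc, p)

cls <- classify_trajectories(tr, frame_interval = 0.02)
round(category_fractions(cls), 3)
#> immobile confined   normal
#>    0.091    0.350    0.559

ctl <- random_walk_control(n_tracks = 2000, seed = 301)
round(100 * ctl$fractions[["confined"]], 1)
#> [1] 30.9
```

The fractions say that with 10% anchored and 45% nanodomain-trapped
molecules simulated, the classifier retains a 9/35/56 immobile/confined/
normal split after R² exclusion; the 30.9% is the false-confinement rate
of the same classifier on pure random walks at the same step scale — the
baseline any measured confined fraction must beat.

The numbered scripts under `analysis/` run the full narrative on this
synthetic system — simulation, video tracking, classification, maps
(density-vs-step-size weighted PCC of −0.52 on the example condensate),
pair-correlation fits, HMM segmentation, and fusion fitting (τ recovered
at 51.0 ms, median error 0.3%, on traces generated at τ = 51 ms) — and
write their tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

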