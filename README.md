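# nanodyn

Single-particle dynamics of plasma-membrane nanodomains in R.

Proteins such as flotillins and hypersensitive-induced-reaction (HIR)
proteins organise into sub-micron plasma-membrane nanodomains whose lateral
mobility, surface density and membrane residence change under biotic and
abiotic stress. Quantifying that behaviour from (VA-)TIRF microscopy takes a
chain of analyses — spot detection, trajectory linking, mean-square-
displacement (MSD) diffusion estimation, dwell-time kinetics, two-channel
colocalization, FRAP recovery and FCS density estimation — that is usually
scattered across instrument software. `nanodyn` implements the whole chain
as tested, scriptable R functions, together with a ground-truthed synthetic
generator so every stage can be validated without raw imaging data.

## What it computes

* **Detection** — sub-pixel spot positions by difference-of-Gaussians
  candidates refined with local 2D Gaussian fits (matching pursuit, two
  passes); intensity, FWHM-square size, per-frame density; Voronoi
  localization-density segmentation (`detect_spots`, `spot_statistics`,
  `compute_density`, `voronoi_segment`).
* **Tracking** — greedy mutual-nearest-neighbour linking with gap closing,
  membrane dwell times with censoring, kymographs
  (`link_trajectories`, `dwell_times`, `make_kymograph`).
* **Dynamics** — time-averaged MSD; per-track `D = slope/4` from the first
  lags; mean instantaneous speed; characteristic peaks **Ĝ** of the
  log₁₀ distribution via a 1-vs-2 component Gaussian mixture selected by
  BIC; exponential dwell-time fits
  (`compute_msd`, `fit_diffusion`, `compute_velocity`,
  `log_binned_peaks`, `fit_dwell_exponential`).
* **Colocalization** — object-based mutual-nearest-neighbour matching with
  a closed-form chance level (`colocalize`, `line_profile`).
* **FRAP** — double normalization, single-exponential recovery kinetics,
  mobile fraction, and per-strip analysis of the bleached region
  (`normalize_frap`, `fit_recovery`, `subroi_recovery`).
* **FCS** — exact multiple-tau autocorrelation, 2D membrane-diffusion fit
  (`G(τ) = G₀/(1 + τ/τ_D)`, `N = 1/G₀`), surface density by the
  correlation and intensity routes
  (`autocorrelate`, `fit_fcs_2d`, `density_from_intensity`).
* **Statistics & pipeline** — Student's t-test comparisons with
  significance codes, plain-text run configs, and a deterministic
  detect→track→dynamics driver (`compare_groups`, `run_pipeline`).
* **Synthetic data** — Brownian emitters with exponential membrane dwell on
  a closed (reflecting) field, rendered as pixel-integrated Gaussian spots
  with Poisson + read noise; two-channel, FRAP and FCS experiments with
  full ground truth (`simulate_movie`, `simulate_two_channel`,
  `simulate_frap`, `simulate_fcs_trace`).

## Worked example

Simulate a movie of membrane particles diffusing at 0.035 µm²/s, run the
pipeline, and look at the recovered mobility:

```r
library(nanodyn)

img <- imaging_spec(pixel_size = 0.1, frame_interval = 0.1,
                    n_frames = 30, shape = c(96, 96))
pop <- population_spec(D = 0.035, mean_dwell = Inf,
                       mean_intensity = 1100, intensity_cv = 0.05)
sim <- simulate_movie(pop, img, density = 0.3, seed = 42)
sim$movie
#> <nd_movie 'ch1'> 96 x 96 px, 30 frames, 0.1 um/px, 0.1 s/frame

res <- run_pipeline(sim$movie)
median(res$dynamics$D)
#> [1] 0.03458567
```

The median per-track diffusion coefficient (0.035 µm²/s) recovers the
generating value within the sampling error expected for 30-frame tracks.
On larger track ensembles, `log_binned_peaks()` reports the characteristic
peaks Ĝ of the distribution and whether one or two subpopulations are
supported:

```r
tr <- simulate_brownian_tracks(500, 50, D = 0.035, dt = 0.1, seed = 1)
Ds <- sapply(split(tr, tr$track_id), function(t1)
  fit_diffusion(compute_msd(t1, frame_interval = 0.1))$D)
log_binned_peaks(Ds[Ds > 0])
#> <nd_peaks> 1 component(s), n = 500 (0 non-positive dropped)
#>     G_hat weight log10_sd se_log10_mu se_G_hat
#> 1 0.03351      1   0.1362    0.006091  0.00047
```

A thin command-line wrapper for simulate/run workflows is installed at
`inst/scripts/nanodyn-pipeline.R`.

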