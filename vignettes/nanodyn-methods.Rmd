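---
title: "Methods and design of the nanodyn pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the nanodyn pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodyn)
```

`nanodyn` analyses single-particle imaging of plasma-membrane nanodomain
proteins recorded by (VA-)TIRF microscopy: it detects diffraction-limited
spots, links them into trajectories, estimates lateral diffusion and membrane
dwell kinetics, decomposes mobility distributions into subpopulations,
quantifies two-channel colocalization and Voronoi localization-density
clusters, and analyses FRAP and FCS recordings.  Because raw imaging data of
this kind are rarely shareable, the package ships a ground-truthed synthetic
generator that reproduces the statistical structure the analysis assumes;
every stage is validated against it and against brute-force oracles.

## The synthetic generator

Particles live on a field extended `margin` px beyond the rendered frame and
perform 2D Brownian motion with per-axis step variance $2 D \Delta t$.
Membrane residence is exponential: a particle's lifetime is drawn from
$\mathrm{Exp}(\tau)$ with `mean_dwell` $= \tau$, discretised to frames
(a particle alive for time $L$ spans $\lfloor L/\Delta t\rfloor + 1$ frames,
so observed dwells carry a $+\Delta t/2$ discretisation offset, below the
recovery tolerances used here).  New particles appear as a Poisson process
with rate (expected count)/(mean dwell), which keeps the expected particle
number stationary; particles alive at the first or last frame are flagged
censored and excluded from dwell fits by default.

The domain boundary is reflecting, making the field a closed reservoir.
This matters only for long recordings without turnover (FRAP): with open
boundaries the field visibly depletes over a minute of simulated diffusion,
which is an artifact of the finite domain rather than membrane physics.

Rendering uses pixel-integrated Gaussian point-spread functions (products of
1D Gaussian integrals over the pixel extent), so the counts deposited by an
emitter equal its assigned intensity up to the mass outside a
$\pm 4\sigma$ window ($<0.03\%$).  Noise follows the EMCCD convention:
Poisson shot noise on signal plus background, then additive Gaussian read
noise.  Defaults — 0.1 µm pixels, 0.1 s frames, PSF $\sigma = 1.3$ px —
are typical for a 100×/1.45-NA TIRF setup; the acquisition calibration of
the motivating experiments is not published, so these are explicit,
configurable stand-ins.

What the generator does **not** emulate: photophysics beyond single-step
disappearance (no blinking or bleaching during life), anisotropic or
anomalous diffusion, membrane topography, and spatially structured
backgrounds.  Passing tests therefore demonstrate correctness of the
*estimators* under the stated model, not robustness to every property of
real recordings.

## Spot detection

Candidates are local maxima of a difference-of-Gaussians band-pass
($\sigma$ and $1.6\sigma$) above `candidate_nsd` robust SDs; maxima closer
than $2\sigma$ are merged keeping the brighter.  Each candidate is refined
by least squares with a 2D Gaussian plus constant background on a
$(6\sigma + 1)$-px window; the window's border ring supplies the starting
background (median).  Fits whose centre leaves the window or whose width
falls outside $[0.5, 2]\,\sigma$ are discarded as divergent.  Detection is
matching-pursuit: accepted spots are subtracted from a working image,
brightest first, and a second pass over the residual recovers the partners
of merged pairs.

The reported SNR is the fitted amplitude over a robust frame-wide pixel
noise estimate (median absolute difference of vertically adjacent pixels
divided by $\sqrt 2$); a 24-pixel local ring is too noisy to threshold on.
Two conventions matter when interpreting the quality metrics:

* the detection threshold must sit clearly below the expected spot SNR —
  spots at SNR 5 thresholded at `snr_min = 5` are lost half the time by
  symmetric fluctuation, so SNR-5 data are analysed with `snr_min = 3`
  (pure-noise false positives are controlled at `snr_min = 5`, the default
  operating point);
* localization error is a single-emitter property, quantified per axis on
  emitters whose nearest true neighbour is $>6$ px away; at SNR 5 the
  observed $\approx 0.19$ px per axis is essentially the Cramér–Rao bound
  for these counts;
* two emitters closer than the 2 px match radius form one
  diffraction-limited spot and are not counted as two detectable targets
  when scoring recall (standard practice in localization benchmarking).

Spot size is reported as the FWHM square side $2\sqrt{2\ln 2}\,\sigma$ px,
the closest standard analogue of the "n × n pixels" footprint convention
used for nanodomains.  Spot density is counts per area (µm² by default,
px² on request), per frame and pooled.

## Trajectory linking

Frame-to-frame assignment is greedy on ascending distance within
`max_disp` px (equivalent to iterated mutual nearest neighbours), with gap
closing over up to `max_gap` missed frames at radius
`max_disp * (gap + 1)`.  At the particle densities this assay operates at
(≈0.15 spots/µm²), greedy linking agrees with an exhaustive
minimum-cost assignment oracle on every tested fixture; the oracle test
guards that equivalence.  The default search radius is
$3\sqrt{4 D_{max} \Delta t}$ for the fastest expected population.  Dwell
time is the inclusive span `(last - first + 1) * dt`; censored tracks are
excluded by default.

## Diffusion, velocity, and characteristic peaks

The time-averaged MSD uses all ordered point pairs at each lag (bit-exact
against a brute-force double loop), and $D$ comes from ordinary least
squares over the first 4 lags with a free intercept absorbing localization
error — the standard SPT bias/variance compromise.  Negative slopes are
clamped to $D = 0$ and flagged rather than erroring, since slow tracks
legitimately produce them.  Velocity is the mean instantaneous speed
(displacement over elapsed time per step); for pure Brownian motion its
expectation is the Rayleigh mean $\sqrt{\pi D/\Delta t}$, which the tests
verify — the definition is stated prominently because µm/s figures for
diffusing particles depend entirely on it.

Subpopulation structure is summarised by the characteristic peak Ĝ: a
Gaussian mixture with 1 or 2 components is fitted to $\log_{10}$ of the
per-track values by EM (k-means initialisation plus random restarts, best
likelihood kept; component SD floored at $10^{-3}$ decades), the component
count is chosen by BIC, and each peak is reported as
$\hat G = 10^{\mu}$ with a standard error from the numerically observed
information.  BIC rather than AIC keeps the 2-component call conservative.
The 30-bin log-spaced histogram is attached for display only; the fit uses
the raw values.  Non-positive $D$ estimates are dropped with their count
reported.  An independent EM implementation (mclust) serves as a
cross-check in the test suite, never as the estimator.

Dwell-time distributions are summarised by a least-squares fit of
$A e^{-t/\tau}$ to the histogram above `fit_floor` (to skip bins truncated
by the minimum observable dwell), cross-checked against the closed-form
maximum-likelihood mean; disagreement or a low $r^2$ flags the sample as
non-exponential.

## Colocalization

Colocalization is object-based: mutual-nearest-neighbour pairs of spot
centres within `match_radius` (default 2 px, the diffraction scale), with
the percentage referred to channel A by default.  The chance level for a
homogeneous second channel is the closed form
$100\,(1 - e^{-\rho_B \pi r^2})$, also available empirically via position
shuffling.  The matched-pair count is symmetric in the channels; only the
denominator changes with the reference.

## FRAP

Recovery traces are double-normalized:
$F(t) = \frac{(\mathrm{roi} - \mathrm{bg})/(\mathrm{ref} - \mathrm{bg})}
{\langle \cdot \rangle_{pre}}$, so acquisition bleaching cancels and the
pre-bleach mean maps to 1.  Kinetics are summarised by the empirical
single-exponential $F(t) = F_0 + (P - F_0)(1 - e^{-kt})$ on post-bleach
samples (the bleach frame itself is excluded; $t=0$ at the bleach), with
mobile fraction $100 (P - F_0)/(1 - F_0)$ and percent recovery evaluated at
the last common timepoint by default.  A diffusion-model fit (Soumpasis) is
deliberately out of scope: the quantities of interest here are percent
recovery and mobile fraction, not $D$ from FRAP.  Three robustness measures
matter in practice and are built in: the fit is multi-started over rate
scales (a single bad $k$ start can strand the optimizer in a degenerate
minimum); when the fitted rate implies the plateau was never approached
within the record ($k\,t_{max} < 0.5$) the recovery level actually reached
replaces the extrapolated plateau and the fit is flagged; and when exchange
across the ROI edge is faster than the frame interval, a freely fitted
$F_0$ settles above the true post-bleach floor and deflates the mobile
fraction by 5–10 points — `fix_F0` pins $F_0$ to the bleach-frame
observation (clean in the simulator, where the bleach frame is rendered
before any exchange), which removes that bias at every immobile fraction
we tested.

Validation on the simulator taught us two lessons that are reflected in the
recommended experiment design.  First, with only a handful of particles in
a small ROI, normalizing each cell by its own noisy pre-bleach mean biases
the averaged curve upward ($E[X/Y] > E[X]/E[Y]$); replicate cells should be
pooled by averaging raw ROI and reference traces first and normalizing
once, which is how the recovery tests and the acceptance script proceed.
Second, the record must out-last the reservoir mixing time
($\approx (L/\pi)^2/D$ for a closed field of size $L$) or the plateau — and
hence the mobile fraction — is an extrapolation; the simulated experiments
use 80 s records (more than twice the mixing time) for this reason, stated
here as the package's own choice of study design.

`subroi_recovery` splits the bleached square into strips ("top, middle,
bottom") and fits each independently; with purely lateral diffusion the
middle strip recovers more slowly than the periphery.  The strip rates are
fitted on the early exchange window (`t_max_fit`), where the strip-level
differences live, because the late record is shared reservoir-scale
relaxation common to all strips.

## FCS

The multiple-tau correlator computes
$G(\tau) = \langle \delta F(t)\,\delta F(t+\tau)\rangle / \langle F\rangle^2$
on a quasi-logarithmic grid: 8 lags per cascade, with pairwise binning
halving the time resolution per cascade.  It is exactly equal (bit-level)
to a direct correlation of the binned traces, which the tests assert.
Traces are split into 4 segments whose correlations are averaged, mirroring
20 s point measurements.  The fit model is 2D membrane diffusion without a
triplet term, $G(\tau) = G_0/(1 + \tau/\tau_D)$, giving $N = 1/G_0$ and
density $N/(\pi w_0^2)$ with a default beam waist $w_0 = 0.25$ µm
(configurable; the calibration of the motivating instrument is not
published).  The simulator defines per-particle emission as
$2\,b\,e^{-2 r^2/w_0^2}$ so that `brightness` $b$ is the area-averaged
counts per particle per sample; with this convention the trace mean is
$N b$ *and* $G_0 = 1/N$ simultaneously, which a plain
$e^{-2r^2/w_0^2}$ profile cannot satisfy.  The intensity route
(total signal / brightness / area) is provided as the correlation-free
alternative; the correlation route is the default.

## Voronoi segmentation

Spots are tessellated (deldir), each receives the local density
$1/\mathrm{cell\ area}$, and spots at or above the density threshold are
joined into clusters through Delaunay adjacency; clusters below
`min_cluster_size` and cells clipped by the bounding region are labelled 0.
Densities are scale-covariant (coordinates scaled by $c$ scale densities by
$1/c^2$) and cell areas partition the bounding region.

## Statistics and reproducibility

Condition-vs-control comparisons use the two-sample Student's t-test
(pooled variance by default, Welch behind a flag) with the conventional
`*`/`**`/`***` codes at 0.05/0.01/0.001; no multiple-testing correction is
applied, and reports say so.  All randomness flows through explicit seeds:
identical seed and parameters give bit-identical movies, and the pipeline
driver writes byte-identical CSVs on repeated runs.  Problem sizes used in
the validation suite (e.g. 500 tracks × 50 steps for diffusion recovery,
2000 values for mixture selection, twenty pooled cells per FRAP condition,
20 s FCS traces) were chosen as the smallest sizes at which the estimators'
sampling noise is clearly inside the stated recovery tolerances.

## Known limitations

* Detection assumes an isotropic Gaussian PSF and a locally constant
  background; structured backgrounds need pre-flattening.
* Greedy linking is not a multiple-hypothesis tracker; above roughly
  1 spot/µm² with fast diffusion its assignments will degrade before a
  global assignment would.
* The single-exponential FRAP model is empirical; its $k$ is a summary
  rate, not a diffusion coefficient.
* The mixture decomposition considers at most two components, matching the
  one-or-two subpopulation structure this assay reports.
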