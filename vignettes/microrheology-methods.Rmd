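---
title: "Methods: intracellular mobility and crowding analysis with crowdmsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intracellular mobility and crowding analysis with crowdmsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmsd)
```

## Scope and model

`crowdmsd` analyses the short-timescale (≲15 s) mobility of point-like
intracellular markers — chromosomal loci and cytosolic aggregates in
bacteria — and relates treatment-induced mobility changes to
macromolecular crowding. Its core quantity is the time-averaged 2-D mean
square displacement

$$\mathrm{MSD}(\tau) = \langle (x(t+\tau)-x(t))^2 + (y(t+\tau)-y(t))^2 \rangle_t,$$

which for these systems is well described by a power law
$\mathrm{MSD}(\tau) = A\,\tau^{\alpha}$ with $\alpha < 1$ (subdiffusion).

The synthetic-data generator uses fractional Brownian motion (fBm) as the
generative motion model. fBm is chosen because it is the simplest
stationary-increment Gaussian process with exactly the observed
$\tau^{\alpha}$ scaling; its Hurst parameter maps to the exponent as
$\alpha = 2H$. Alternatives (continuous-time random walks, confined
ordinary diffusion) produce superficially similar MSDs but different
increment correlations and are out of scope. Sampling uses circulant
embedding of the fractional-Gaussian-noise covariance, which is exact (no
small-lag bias) and fast; one complex FFT yields both coordinates.

"Amplitude" throughout is the full 2-D MSD prefactor; each coordinate
contributes $A/2\,\tau^{\alpha}$. Movies are 2-D projections, so all
analysis is 2-D; if a per-axis convention is preferred, all amplitudes
halve and every comparison statistic (fold change, exponent, slopes) is
unchanged.

## What the generator emulates — and what it does not

Defaults are calibrated to the magnitudes reported for live *E. coli*:

* Chromosomal loci: $\alpha = 0.4$, amplitudes placing MSD(10 s) at
  $4.0\times10^{-3}$ µm² (origin-proximal) and $2.5\times10^{-3}$ µm²
  (terminus-proximal); cytosolic aggregates an order of magnitude faster
  (MSD(10 s) ≈ 0.08 µm²). See `marker_defaults()`.
* Frame interval 0.1 s and 150 frames (15 s span), covering the lag range
  0.1–14 s used for comparisons. The acquisition rate of the original
  experiments is not published; these values were fixed once from the
  analysed lag range.
* Confinement in a 2-D spherocylinder (default 3 µm × 1 µm) by increment
  reflection; photobleaching $I(t) = I_0 e^{-t/\tau_b}$ (default
  $\tau_b = 50$ s); localization noise per coordinate with SD
  $\sigma_0\sqrt{I_\mathrm{ref}/I(t)}$ (default $\sigma_0$ = 20 nm), the
  photon-limited scaling, which adds the lag-independent $4\sigma^2$
  offset to measured MSDs.
* Rendering: pixel-integrated Gaussian point-spread function (σ = 0.13 µm
  on 0.1 µm pixels), uniform background, Poisson shot noise. No EMCCD
  excess noise, no 3-D PSF, no phase-contrast channel, no cell growth or
  division — passing tests on these movies therefore demonstrates the
  correctness of the analysis chain, not robustness to every artefact of
  real microscopy.
* Drift is off by default: sub-10 s displacements are treated as
  fluctuations; directed segregation motion matters only on minute
  timescales.
* Assay tables: per-condition true biomass/OD (control default
  0.45 mg·mL⁻¹·OD⁻¹), protein fraction (0.55), cell refractive index
  (1.388 vs medium 1.335), with multiplicative Gaussian noise (CV 0.05)
  over three biological × three technical replicates — the replicate
  structure of the corresponding wet assays. BSA titrations decrease
  linearly in concentration and cross zero exactly where medium and cell
  RI match; the BSA refractive increment defaults to the standard protein
  value dn/dc = 0.185 mL/g.

Seeding: one master seed; every track, condition, replicate and noise
stream derives its own seed by stable hashing of the master seed and the
unit's labels (`derive_seed()`), so results are independent of generation
order and bit-reproducible.

## Tracking

Detection is difference-of-Gaussians band-pass filtering at the PSF scale
(via EBImage), deterministic 8-neighbour local maxima, an SNR gate
(default 5, in robust MAD units of the smoothed frame), and subpixel
refinement by least-squares fitting of a pixel-integrated 2-D Gaussian
with free position, intensity, background and width. The integrated model
matches the renderer exactly, so noiseless localization is accurate to
well below 0.01 px; the fitted intensity feeds the marker-effect
correction. Saturated windows fall back to a flagged centroid. Pixel
centres sit at integer coordinates, origin at the image corner, and
µm = px × pixel size — stated explicitly because no convention is
universal.

Linking is greedy nearest-neighbour frame-to-frame assignment with a hard
displacement gate and optional gap bridging; gap frames are flagged and
excluded from MSD pairs. With a few spots per cell, greedy assignment is
in practice identical to globally optimal assignment; dense fields are a
documented limitation. Ties break deterministically (lower detection
index), making detect→link→filter a pure function of the movie.

## MSD analysis and the marker-effect correction

`time_averaged_msd()` averages all overlapping pairs per lag, drops lags
with fewer than `min_pairs` (default 5) valid pairs, and records pair
counts; it is verified against an $O(n^2)$ brute-force enumeration on
random tracks. Power laws are fitted by ordinary least squares of
log MSD on log τ over a window defaulting to 0.1–10 s — the fluctuation
regime — with lags of non-positive MSD excluded and fits refused below 4
usable lags. `msd_at_lag()` interpolates log-log (exact for power laws)
and refuses extrapolation. Exponents are fitted on ensemble curves;
per-track fits are available but noisy.

Long acquisitions bleach markers, and marker brightness varies between
spots. The correction implemented in `correct_marker_effects()` addresses
the two resulting biases with the standard photon-limited localization
model: (i) regression of shortest-lag MSD on 1/intensity across tracks
estimates the static-error offset $4\sigma^2(I)$, which is subtracted at
all lags (it is lag-independent); (ii) regression of log provisional
amplitude on log intensity removes any residual systematic
amplitude–brightness trend by rescaling each curve to a reference
intensity. Each step runs only when its calibration slope is
statistically distinguishable from zero (p ≤ 0.05) and at least 20 tracks
spanning a 2-fold intensity range are available; otherwise curves pass
through unchanged and the decision is logged. The published correction
this emulates is specified only by its purpose (photobleaching and
marker-size effects); the two-step procedure here is this package's
interpretation and is validated against synthetic ground truth, where it
restores the noiseless ensemble MSD within 10% at all lags ≥ 2 frames.

## Condition statistics

The biological replicate is the experimental unit: per-track MSD(τ*)
values (τ* = 10 s by default, arbitrary but fixed) are reduced to
replicate medians — medians because per-track MSD distributions are
right-skewed — then summarized as mean ± SE across replicates. A single
replicate reports SE as missing, never zero. Fold changes are
log(treated/control) of the means; base 10 for mobility panels, base 2
when plotted against crowding, both exposed as parameters since
conventions differ. Significance defaults to the Mann–Whitney test for
MSD-derived quantities (skewed) and Welch's t for assay ratios; both are
available everywhere, and no multiple-testing correction is applied by
default (raw p-values are reported; Benjamini–Hochberg can be applied by
the user via `p.adjust`).

Cross-marker agreement is quantified against the identity line with a
total-least-squares slope — symmetric in the two markers, unlike ordinary
regression — plus Pearson correlation and the RMS perpendicular distance
to $y = x$. The same estimator, against a slope of −1, serves the
crowding–mobility scatter.

## Crowding estimators

Biomass/OD and protein-fraction ratios average technical replicates
within biological replicates before any cross-replicate statistics, then
propagate ratio SEs to first order:
$SE_{a/b} = (A/B)\sqrt{(SE_a/A)^2 + (SE_b/B)^2}$ — exact to the delta
method, verified on simulated Gaussians. RI matching fits the OD-vs-BSA
titration line and converts the zero crossing to a refractive index; a
non-decreasing series is refused since OD must fall as the medium
approaches index match. Whether the crowding axis of the
mobility-crowding scatter is linear or logarithmic is not standardized;
both the linear ratio and log₂ are computed, with log₂ used for the slope
so the two axes are symmetric.

## Numerical and design choices

* Circulant-embedding eigenvalues are clipped at tiny negative values
  (floating point); genuinely negative eigenvalues abort, but cannot occur
  for fGn with $H < 1$.
* Confinement reflects increments; steps longer than a cell diameter
  (pathological amplitudes) clamp to the boundary.
* Zero-intensity frames make localization noise undefined; they are
  flagged as gaps rather than given arbitrary positions.
* The fold-change recovery test pairs treated and control simulations by
  common random numbers (same per-track seeds, scaled amplitude), so the
  statistics chain is tested without Monte-Carlo confounding; an
  independently seeded variant is checked at 3 SE.
* The synthetic crowding-slope study uses six conditions spanning
  biomass-ratio factors 0.70–1.40 — wider than the four real treatments —
  chosen a priori so the slope estimate has useful leverage at CV 5% with
  triplicate averaging.
* An empty or partial configuration is valid: every field has a
  documented default (`default_run_config()`), and validation rejects
  unknown keys and unphysical values with path-qualified messages. A
  configuration lacking a control condition is rejected, since every
  treated condition needs its control counterpart at the same treatment
  time.

## Problem sizes

Test and demonstration runs use sizes chosen to exercise every code path
at interactive speed: 2000 × 150-frame tracks for exponent recovery,
60-track batches for the correction study, four-spot 70×70 px movies for
tracking fidelity, and a demo experiment of 2 markers × 4 conditions × 2
treatment times × 3 replicates × 12 tracks. All scale linearly if larger
studies are needed.

## Known limitations

* No cell segmentation: tracks are assigned to cells only through
  metadata. No 3-D tracking, velocity autocorrelation, step-size
  distribution analysis or CTRW/fBm model selection.
* Greedy linking degrades in dense spot fields.
* The marker-effect correction assumes the photon-limited noise model and
  a log-linear amplitude–intensity trend; other marker artefacts (e.g.
  aggregate size polydispersity coupling to mobility nonlinearly) are not
  modelled.
* Real treated-versus-control measurements on live cells involve
  biological variability the generator does not emulate; the package
  validates the measurement chain, not biological conclusions.
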