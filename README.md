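# crowdmsd

Single-particle-tracking microrheology and macromolecular-crowding analysis
for bacterial cells, with a fully ground-truthed synthetic-data generator.

## The problem

Short-timescale (sub-15 s) motion of intracellular markers — fluorescently
tagged chromosomal loci near the replication origin and terminus, and inert
cytosolic protein aggregates — is a sensitive microrheological probe of the
bacterial cytoplasm. Sub-lethal antibiotic treatments and osmotic shocks
shift this mobility by small but consistent amounts, and those shifts track
changes in intracellular density (macromolecular crowding). Quantifying
them requires a chain of steps, each easy to get subtly wrong: spot
detection and linking in noisy fluorescence movies, time-averaged mean
square displacements with gap handling, corrections for photobleaching-
driven localization error and marker-size effects, replicate-structured
condition statistics, and density proxies from plate-reader assays.

`crowdmsd` implements that chain as composable, tested R functions, for
microscopists and quantitative biologists who want to analyse their own
tracking data — or to validate an analysis end-to-end on simulations where
the truth is known.

## The model

Marker motion is modelled as 2-D fractional Brownian motion. The mean
square displacement at lag time τ is

    MSD(τ) = ⟨(x(t+τ) − x(t))² + (y(t+τ) − y(t))²⟩ = A · τ^α ,

with anomalous-diffusion exponent α = 2H (H the Hurst parameter);
0 < α < 1 is subdiffusion, α = 1 ordinary diffusion. Chromosomal loci in
bacteria show α ≈ 0.4. Static localization error adds a lag-independent
offset 4σ² to the 2-D MSD, with σ² ∝ 1/(photon count), which is what the
marker-effect correction estimates and removes.

Condition-level statistics follow the replicate-median design: MSD(τ*) per
track (τ* = 10 s by default), medians within biological replicates, mean ±
standard error across replicate medians, and treated-to-control fold
changes log(MSD_treated/MSD_control). Crowding is proxied by the
biomass-to-OD600 ratio and the cell refractive index from BSA
index-matching titrations; ratio standard errors propagate as
SE_{a/b} = (A/B)·sqrt((SE_a/A)² + (SE_b/B)²). Inverse proportionality
between mobility and crowding appears as a slope of −1 in log₂–log₂
coordinates, estimated by total least squares.

## Worked example

Simulate 200 subdiffusive locus-like tracks, compute the ensemble MSD and
recover the motion parameters:

```r
library(crowdmsd)

cfg <- sim_config(n_tracks = 200, n_frames = 150, hurst = 0.2,
                  amplitude = marker_defaults()$Ori2$amplitude,
                  loc_noise_sigma = 0, seed = 42)
tracks <- generate_tracks(cfg, confine = FALSE, bleach = FALSE, noise = FALSE)
ens <- ensemble_msd(tracks)
fit_power_law(ens, c(0.1, 10))
#> Power-law MSD fit: MSD(tau) = 0.00159 * tau^0.421  (r^2 = 0.9961, 100 lags in [0.1, 10] s)
msd_at_lag(ens, 10)
#> [1] 0.004369...
```

The fitted exponent 0.421 recovers the generative α = 2H = 0.4 up to
Monte-Carlo error, the amplitude 0.00159 µm²·s⁻⁰·⁴ matches the configured
origin-proximal locus default, and MSD(10 s) ≈ 4.4×10⁻³ µm² sits at the
expected magnitude for such loci.

The whole pipeline — simulation, MSD analysis, condition statistics and
crowding assays — runs from one config:

```r
demo <- system.file("extdata", "demo_config.yaml", package = "crowdmsd")
run_pipeline(demo, output_dir = "demo-out")
read.csv("demo-out/fold_changes.csv")
```

In the demo experiment the sorbitol-like condition (mobility scaled by
1/1.3, crowding up 30%) yields log₁₀ fold changes of −0.143 (locus) and
−0.150 (aggregate) at the late treatment time, and the crowding-versus-
mobility scatter has a total-least-squares slope of −1.03 — the inverse-
proportionality signature the pipeline is designed to detect. A thin CLI
wrapper is provided in `inst/scripts/crowdmsd-cli.R`.

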