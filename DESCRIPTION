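Package: crowdmsd
Title: Single-Particle Tracking Microrheology and Macromolecular Crowding
    Analysis for Bacterial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for short-timescale intracellular
    mobility in bacteria. Generates ground-truthed synthetic data (fractional
    Brownian motion trajectories confined to a spherocylindrical cell,
    rendered fluorescence movies with photobleaching and shot noise, and
    plate-reader style biomass/optical-density assay tables), detects and
    links fluorescent spots into trajectories, computes time-averaged mean
    square displacements with corrections for photobleaching-driven
    localization error and marker-size effects, fits anomalous-diffusion
    power laws, aggregates mobility per treatment condition with fold
    changes and significance tests, and estimates macromolecular crowding
    from biomass-to-OD ratios, refractive-index matching titrations and
    protein fractions, correlating crowding changes with mobility changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    jsonlite,
    tiff,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
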