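Package: rollflow
Title: Rolling-Adhesion Analysis of Tumor Spheroids Under Microfluidic Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tethering, rolling and firm adhesion of multicellular
    tumor spheroids perfused over an adhesive monolayer in a parallel-plate
    microfluidic channel at ascitic shear stress (0.03-0.15 dyn cm-2).
    Provides closed-form channel hydrodynamics (wall shear stress, near-wall
    spheroid transport velocity), a stochastic catch-slip bond simulator that
    generates ground-truthed spheroid trajectories and rendered fluorescence
    time-lapse stacks, spheroid detection and frame-to-frame track linking,
    motion classification into tethering / rolling / adhesion with cohort
    percentages and rolling velocities, stepwise shear-ramp detachment
    analysis, and the cohort statistics (chi-square, one-tailed Student t,
    median fold changes) used to compare conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
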