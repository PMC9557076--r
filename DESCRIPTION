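Package: funlge
Title: Cardiac Phase-Resolved Synthetic Late Gadolinium Enhancement Imaging
Version: 0.1.0
Authors@R:
    person("funlge", "maintainers", email = "funlge@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for cardiac phase-resolved
    ("functional") late gadolinium enhancement (LGE) imaging. Plans the
    per-cardiac-phase inversion-time sampling realized by a prospectively
    triggered Look-Locker FLASH scheme with multiple inversion-pulse offsets,
    simulates the pulsed longitudinal magnetization on digital phantoms,
    performs voxel-wise polarity restoration and two-parameter
    inversion-recovery fitting to obtain semi-quantitative T1* maps per
    cardiac phase, synthesizes LGE contrast at a single retrospectively
    chosen virtual inversion time, and computes contrast-to-noise and
    contrast-homogeneity metrics across the cardiac cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
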