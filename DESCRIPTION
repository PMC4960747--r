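Package: famousr
Title: Macromolecule-Suppressed Glutamate Editing for 7T MR Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, automated processing and absolute quantification for
    frequency-selective inversion (FSI) difference editing of glutamate at
    2.35 ppm with double-inversion-recovery macromolecule nulling (the FAMOUS
    SVGS five-spectrum scheme). Provides Bloch simulation of shaped inversion
    pulses, optimization of metabolite-nulling delays, a synthetic
    multi-channel acquisition generator with eddy-current and noise models,
    the automated post-processing chain (coil combination, eddy-current
    phase correction, apodization, Fourier transform, automated phasing),
    water-referenced absolute concentration with editing-efficiency
    bookkeeping, the two-voltage B1 reference calibration, and test-retest
    repeatability statistics (one-way random ICC with exact-F confidence
    intervals, coefficient of variation, scan differences).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
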