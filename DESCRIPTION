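Package: metasers
Title: Plasmonic Metasurface Design and Correlative SERS Analysis for
    Single-Vesicle Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-form quasistatic modelling of plasmon resonance on a
    periodically modulated thin metal film (flexible metasurface), obtained by
    conformally mapping a hollow metal nanocylinder onto a grating profile.
    Computes resonance conditions, local-field enhancement maps and
    surface-enhanced Raman scattering (SERS) gain factors, and provides the
    companion analysis pipeline for SERS-based sensing: spectral baseline
    estimation, band intensity and noise measurement, signal-to-noise limit
    of detection from dilution series, Raman band assignment for
    exosome-like spectra, seeded synthetic-data generators, and a
    correlative AFM/SSRM procedure that classifies surface sites as
    exosomes, metal-deposition defects or substrate imperfections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
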