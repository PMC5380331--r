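Package: hscadhesion
Title: Quantitative Adhesion Analytics for Stem Cells on Ligand-Functionalized Supported Membranes
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis suite for quantifying hematopoietic stem and progenitor
    cell adhesion to supported lipid membranes presenting adhesion ligands at
    controlled mean spacing. Provides the ligand-spacing model d = sqrt(A/x),
    Hill fits of the adhesion unbinding transition, reflection interference
    contrast microscopy (RICM) height reconstruction and tight-adhesion area
    measurement, pressure-wave detachment analytics (pulse-energy calibration
    and the critical detachment pressure P*), and contour-fluctuation
    spectroscopy of cell shape dynamics (amplitude maps, spatio-temporal
    autocorrelation, Fourier mode power spectra, motion classification).
    Seeded synthetic generators emulate every input so the full pipeline is
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
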