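Package: letfilm
Title: Track- and Dose-Average LET of Electron Fluence Spectra and
    Radiochromic Film Relative Efficiency
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising the response of radiochromic dosimetry
    films (Gafchromic EBT3 and MD-V3) to low-energy photon beams in terms of
    linear energy transfer (LET).  Computes restricted and unrestricted
    electron collision stopping powers for arbitrary elemental compositions,
    track-average and dose-average LET of binned electron-fluence spectra
    including the track-end term, photon beam quality (half-value layer to
    effective energy), and film relative efficiency from net-optical-density
    dose-response curves.  A seeded synthetic-data module emulates Monte Carlo
    fluence tallies and film calibration curves so the whole pipeline is
    testable without transport simulations or film experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
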