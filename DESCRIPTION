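Package: teerfit
Title: Equivalent-Circuit TEER Extraction and Barrier Analytics for
    Sensorized Barrier-on-Chip Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring barrier integrity in microfluidic
    barrier-on-chip devices with integrated electrodes. Models two-electrode
    impedance spectra with series/parallel networks of resistors and
    constant-phase elements, fits them with a Powell direction-set optimizer
    on a relative-amplitude objective, and extracts area-normalized
    trans-endothelial electrical resistance (TEER). Also computes apparent
    permeability coefficients from tracer assays with calibration-curve
    inversion, analytic fully developed laminar flow and wall shear stress in
    rectangular perfusion channels, and seeded synthetic data generators
    (staged Bode spectra, tracer assays, drug-crossing time courses) for
    end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
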