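Package: chirpmir
Title: Simulation and Chemometric Mapping for Chirped-Pulse Upconversion
    Mid-Infrared Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A physics-based forward simulator and analysis toolchain for
    scanless mid-infrared hyperspectral chemical imaging by chirped-pulse
    sum-frequency upconversion.  Simulates a broadband sub-cycle MIR source,
    Beer-Lambert transmission through Lorentzian absorbers with
    Kramers-Kronig-consistent phase (free-induction-decay tails), type-I
    sum-frequency generation through thin GaSe films with Sellmeier-based
    phase matching, chirped-pulse spectral encoding, and a 12-bit
    hyperspectral camera model.  Provides the matching spectral retrieval
    (delay-domain parabolic-phase correction of the cross-phase-modulation
    artifact, CO2 wavenumber calibration) and hyperspectral-cube
    chemometrics: additive averaging, normalized difference spectral index
    maps, spectral angle mapper classification, Fisher linear discriminant
    mapping, constrained teaching-region sampling, and 10-90% edge-response
    resolution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    withr,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
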