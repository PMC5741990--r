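Package: trfnirs
Title: Time-Resolved fNIRS Motor-Imagery Communication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved functional near-infrared
    spectroscopy (TR-fNIRS) motor-imagery brain-computer interfacing.
    Converts distributions of time-of-flight of photons (DTOFs) into
    statistical moments, conditions the mean time-of-flight signal
    (motion-artifact reduction, band-stop filtering, detrending),
    translates two-wavelength moment changes into oxy- and deoxyhemoglobin
    concentration changes via Monte Carlo layered-slab sensitivity factors,
    and decodes yes/no answers from a block-design motor-imagery paradigm
    with a support-vector activation classifier trained on simulated data.
    Includes a synthetic-data module spanning moment-level activation/rest
    series and full DTOF-level recordings from a layered head model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
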