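Package: phasetomo
Title: Simulation and Optimisation of Propagation-Based X-Ray Microtomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulate-corrupt-correct-reconstruct-score toolkit for
    parallel-beam, inline (propagation-based) phase-contrast X-ray
    microtomography of soft tissue. Provides closed-form acquisition
    planning (Fresnel-regime propagation-distance bounds, angular
    Nyquist projection counts, tiled-scan estimates), seeded digital
    phantoms of embedded spinal-cord and wire-standard samples as paired
    refractive-index decrement/absorption (delta/beta) maps, a Fresnel
    forward model with photon statistics and injectable acquisition
    artefacts (zingers, ring seeds, radial lens distortion), the matching
    pre-reconstruction correction chain, Paganin single-distance phase
    retrieval with filtered back projection, and image-quality metrics
    (peak signal-to-noise ratio, RMS contrast) driving projection-number,
    propagation-distance and delta/beta screening studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
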