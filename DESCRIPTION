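Package: motorpaint
Title: Motor-Based Super-Resolution Mapping of Microtubule Polarity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for motor-PAINT, a
    super-resolution assay in which purified plus-end-directed kinesin
    motors walk over a fixed cytoskeleton and their tracked binding events
    reconstruct microtubules together with their polarity. Provides a
    ground-truthed synthetic-movie generator (microtubule networks, motor
    kinetics, camera forward model), single-molecule localization with
    Laplacian-of-Gaussian detection and Levenberg-Marquardt Gaussian
    fitting, cross-correlation drift correction, nearest-neighbor track
    linking with angle filtering, track orientation classification,
    super-resolved reconstruction, overlap-correlation and segment-ratio
    polarity statistics, and a closed-form plus Monte-Carlo model of
    kinesin cargo distribution on mixed-polarity microtubule bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    minpack.lm,
    EBImage,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
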