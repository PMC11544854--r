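Package: octburnscore
Title: Burn Depth Scoring of Pediatric Hand Burns from Optical Coherence
    Tomography Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an additive 0-6 burn depth score for pediatric hand
    burns built from four optical coherence tomography (OCT) and dynamic OCT
    features (surface irregularity, epidermal loss, dermal pattern, and
    microvascular network), together with cohort-level diagnostic evaluation
    (confusion tables, predictive values with Wilson or exact confidence
    intervals, threshold sweeps, inter-observer agreement), a synthetic
    cohort generator with two-observer grading noise, and a synthetic
    OCT/D-OCT phantom renderer with automated feature graders so the whole
    image-to-score pipeline can be tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
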