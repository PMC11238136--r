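Package: screenCascade
Title: Quantitative Analytics for Protein-Abundance Reporter Drug Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for the screening cascade used to discover
    compounds that downregulate a luminescent protein-abundance reporter and
    sensitize cells to PARP inhibition: plate normalization and Z-factor
    quality control, B-score hit calling via two-way median polish, viability
    counter-screening with a cytotoxicity ratio filter, dose-response fitting
    with normalized area-under-curve combination calls, and zero-interaction
    potency (ZIP) synergy scoring of dose-combination matrices. Includes a
    synthetic plate-screen generator with known ground truth so every stage
    of the cascade can be validated end to end without raw screen data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
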