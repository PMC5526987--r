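Package: haloquant
Title: Quantification of DNA Halo (MFHR) Micrographs
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures DNA halos produced by the maximum fluorescence halo
    radius (MFHR) assay from 8-bit fluorescence micrographs. Detects
    candidate halos, applies maxima-relative residual-nucleus (RN) and
    absolute or maxima-relative outer thresholds, and returns linked RN and
    outer areas with equal-area-circle radii. Classifies halos into
    stability classes Ia (bright RN), Ib (pale RN) and II (unmeasurable RN),
    quantifies photo-induced halo decay over timed image series with
    censoring, and provides population summaries and threshold-calibration
    procedures. A synthetic phantom generator with closed-form
    threshold-crossing ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    png,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
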