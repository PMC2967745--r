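Package: clinarica
Title: Independent Component Analysis of Clinical Laboratory Clinarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-by-biomarker matrices ("clinarrays") from
    longitudinal clinical laboratory records by per-patient median
    aggregation, prunes sparsely measured patients and biomarkers, imputes
    remaining gaps by weighted k-nearest-neighbour imputation, and
    decomposes the standardized matrix with an ensemble of FastICA runs to
    extract latent physiological factors. Significant biomarkers are
    identified by two consensus rules applied across the ensemble (a
    top-fraction rule on mean absolute loadings and an argmax-consistency
    rule) and the agreement between them is reported. A synthetic-data
    generator with planted latent-factor structure supports end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
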