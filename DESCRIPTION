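Package: boxelcycle
Title: Local Cell-Cycle Length Mapping from Dual Thymidine-Analogue Labelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures local cell-cycle length in 3D tissue from dual
    thymidine-analogue (e.g. IdU/CldU) labelling of serial fluorescence
    sections. Implements the differential exposure time estimator
    (T_C = GF * dT / dF), per-section nuclei detection with fused-object
    splitting, per-nucleus analogue classification with per-experiment
    threshold calibration and detection-deficit compensation, boxel-wise
    labelling indices with Abercrombie cell-size estimation, and k-means
    phenotype clustering of boxels. Includes a seedable population
    simulator and a synthetic section-image phantom generator with ground
    truth, so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
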