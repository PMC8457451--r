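Package: nucleomorph
Title: Nuclear Morphometry and Classification of PTC-Like Nuclei in H&E Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-based discrimination of thyroid tumors with and without
    papillary thyroid carcinoma (PTC)-like nuclei from hematoxylin-and-eosin
    histology tiles. Post-processes nucleus instance segmentations with a
    per-image median-area filter, extracts 36 per-nucleus morphometric
    features (23 color, 4 shape, 9 spatial, including gray-level
    co-occurrence texture and nuclear crowding), aggregates them to 72
    per-patient features, and selects classifiers by stratified nested
    cross-validation with chi-squared or sequential forward feature
    selection. Includes an expert-panel agreement analysis (majority-vote
    label derivation, mean pathologist rating, agreement-threshold curves)
    and a synthetic H&E-like image generator with ground-truth masks so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    jsonlite,
    png,
    pracma,
    purrr,
    ranger,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    patchwork,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
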