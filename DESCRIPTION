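Package: bucketforest
Title: Batch-Robust Bucketing of LC-MS Peak Data with Random-Forest
    Authentication and All-Relevant Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns centroided liquid chromatography-mass spectrometry (LC-MS)
    peak lists into a standardized feature matrix by summing peak intensities
    on a fixed retention-time by mass grid ("bucketing") and normalizing each
    sample by its total bucket intensity, so that samples processed in
    different batches share one feature space.  On top of the bucketed matrix
    it provides class-weighted random-forest classification evaluated by the
    out-of-bag error, Boruta-style all-relevant feature selection against
    permuted shadow features, confusion-matrix metrics, PCA batch diagnostics
    and exclusive-intersection (UpSet-style) comparison of the features
    selected for different authentication questions.  A synthetic multi-batch
    cohort generator with planted marker compounds and day-wise batch effects
    supports end-to-end testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
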