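Package: usvpipe
Title: Detection, Classification and Clustering of High-Frequency Primate
    Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for analysing high-frequency
    and ultrasonic vocalizations (5-50 kHz) of the gray mouse lemur: synthesis
    of annotated test scenes emulating archive recordings under four recording
    quality scenarios (good, clipped, low-amplitude, overlaid), spectrogram and
    peak-frequency contour measurement with tonality-based cleaning,
    duration-stratified call detection, fragment/doublet post-filtering and a
    trainable noise classifier, supervised call-type classification, k-means
    clustering with elbow-method model selection, and a validation harness
    computing precision and recall under automated and semi-automated scoring
    with a false-positive taxonomy (noise, fragment, cluster, overlaid).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
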