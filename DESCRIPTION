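Package: smadtrace
Title: Single-Cell Analysis of SMAD Nuclear Translocation and ctgf
    Transcriptional Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dual-reporter bioluminescence
    time-lapse recordings of TGF-beta signaling in single cells. Provides a
    phenomenological generator of two-channel (Nluc-tagged SMAD4/2, Fluc
    ctgf knock-in) single-cell traces and movies with known ground truth;
    nuclear segmentation, cell tracking and trace extraction for rendered
    movies; channel cross-talk correction; per-cell response features
    (nuclear-to-cytoplasmic ratio, basal and peak levels, response
    amplitudes and fold changes, initiation and return-to-basal timing);
    transient-versus-sustained classification of ctgf responses by k-means
    clustering under correlation distance with silhouette validation; and
    dose-response summaries and class-fraction statistics. All user-facing
    functions operate on data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
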