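Package: rppgroi
Title: Facial Region-of-Interest Evaluation for Remote Photoplethysmography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking facial regions of interest (ROIs) for
    camera-based heart-rate measurement. Ships 28 anatomically defined facial
    ROIs expressed as 468-point face-mesh keypoint polygons, extracts mean RGB
    traces from video frames, converts them to pulse signals with four classic
    rPPG algorithms (CHROM, POS, LGI, OMIT), estimates heart rate per sliding
    window by Welch spectral analysis, and scores ROIs with MAE, windowed
    Pearson correlation, masked-spectrum SNR, a min-max normalized overall
    score, acceptance rates, and Bland-Altman agreement. A synthetic study
    generator produces pulse-modulated RGB traces, rendered frames, and ground
    truth so the full pipeline is testable without video datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
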