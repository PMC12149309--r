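Package: esvtbcg
Title: Hankel-SVD Soft-Threshold Denoising and Heart-Rate Validation for Ballistocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for denoising ballistocardiogram (BCG) recordings with an
    iterative Hankel-matrix singular-value soft-thresholding scheme (a
    Cadzow/SSA-style alternating projection), together with the simulation
    machinery used to tune it: a sum-of-sinusoids synthetic BCG generator with
    a respiratory component and calibrated Gaussian noise, SNR grid search over
    threshold and iteration count, and a wavelet soft-threshold baseline for
    benchmarking. Also provides J-peak/R-peak detection, heart-rate estimation,
    Bland-Altman agreement statistics between BCG- and ECG-derived heart rate,
    and readers/writers for a published BCG dataset layout (per-recording
    signal and peak-annotation CSV files plus a subject metadata table).
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
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
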