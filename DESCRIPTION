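Package: restid
Title: EEG Biometrics from Resting-State Signals with Evolutionary Channel Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds per-subject one-class biometric models from resting-state
    EEG. Signals are re-referenced to the common average, segmented into
    one-second instances, and decomposed per channel by empirical mode
    decomposition (with Minkowski-distance selection of the two closest
    intrinsic mode functions) or by a three-level bior2.2 discrete wavelet
    transform. Each sub-band is summarised by instantaneous energy, Teager
    energy, and the Higuchi and Petrosian fractal dimensions, giving 8 (EMD)
    or 16 (DWT) features per channel. One model per subject (local outlier
    factor or one-class SVM) yields true-acceptance and true-rejection rates
    against cohort intruders, and a from-scratch NSGA-III optimizer over a
    mixed binary/integer/real chromosome searches for minimal channel subsets
    that keep both rates high. A synthetic-cohort generator with planted
    informative channels supports download-free end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    FNN,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    readr
Config/testthat/edition: 3
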