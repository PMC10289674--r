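Package: spikeprec
Title: Spike Timing Precision of Motor Codes from Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the temporal precision of spike-timing codes for
    continuous motor output. Implements continuous Kraskov-Stoegbauer-
    Grassberger (KSG) k-nearest-neighbour mutual information estimation
    between within-cycle spike times and motor-output principal-component
    scores, with progressive corruption of spike times by uniform noise to
    locate the timescale at which timing information is destroyed. Provides
    a discrete comparison method based on spike-word binning and
    Nemenman-Shafee-Bialek (NSB) Bayesian entropy estimation with
    surrogate-shuffling bias correction, three precision-selection rules,
    synthetic data generators with ground-truth precision fixed by rounding,
    and cycle segmentation of periodic force/torque recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
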