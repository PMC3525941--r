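Package: streambci
Title: Two-Class Auditory Streaming Brain-Computer Interface Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for two-class auditory streaming
    brain-computer interfaces, in which a listener encodes a binary choice by
    attending to one of two dichotically presented tone streams. Provides
    stimulus scheduling for fixed-phase and drifting-phase stream designs,
    synthesis of attention-modulated event-related potentials in pink noise,
    the online decoding chain (Butterworth band-pass filtering, stimulus-locked
    epoching, running difference-of-averages features, spatially whitened
    L2-regularized logistic regression), a continuous-control signal chain,
    sensitivity-index and signed r-squared feature audits, exact nonparametric
    tests, and orchestrated experiments comparing the two stream designs and
    estimating chance-level performance via backward playback.
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
    utils
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
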