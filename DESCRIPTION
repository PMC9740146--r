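Package: eegauth
Title: EEG-Based User Authentication with Channel Ranking and Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for electroencephalography (EEG) biometric
    authentication and electrode-montage reduction. Recordings are
    zero-phase Butterworth filtered into the canonical delta, theta,
    alpha, beta and gamma sub-bands, segmented into overlapping windows,
    and summarised by a per-channel set of time-domain, Hjorth and
    entropy features. A genuine-versus-imposter random forest is trained
    on SMOTE-rebalanced feature tables, channels are ranked by
    gradient-boosted impurity importance, and a sequential ablation
    locates the smallest montage whose accuracy stays within a
    1-percentage-point tolerance of the full-channel benchmark. A seeded
    synthetic-cohort generator with planted band- and channel-specific
    subject signatures supports end-to-end testing without external
    recordings.
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
    ranger,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
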