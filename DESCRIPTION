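Package: dfcstates
Title: Dynamic Functional Connectivity States from Sliding-Window Correlations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of recurrent dynamic functional connectivity (DFC) states
    from regional fMRI time series. Implements sliding-window Pearson correlation
    with Fisher z-transformation over a 10-ROI parcellation spanning the dorsal
    attention, default mode and frontoparietal networks; majority-rule selection of
    the number of states across a panel of cluster-validity indices; k-means state
    estimation with deterministic seeding and restart control; optimal centroid
    matching between solutions; fractional-occupancy and transition statistics; and
    linear mixed-effects testing of condition-by-state occupancy differences with
    Bonferroni-adjusted estimated-marginal-mean contrasts. A multi-subject synthetic
    cohort generator with planted covariance states and Markov switching provides
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    emmeans,
    Matrix,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
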