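Package: leansim
Title: Neuromechanical Simulation and Analysis of Voluntary Lean
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and analysis of center-of-pressure (COP)
    trajectories recorded during multi-directional voluntary lean
    (limit-of-stability protocols). The body is modelled as a single
    inverted pendulum about the ankle driven by a minimum-jerk reference
    trajectory and a blended feedforward/feedback postural controller.
    Provides five-phase segmentation of COP trials (preparation, planning,
    anticipatory postural adjustment, reaching, returning), subject-specific
    identification of control gains from APA size and maximal lean,
    synthetic cohort generation for Parkinson's disease versus healthy
    comparisons, and the accompanying group-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
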