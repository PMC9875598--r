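Package: dbsep
Title: Stimulation-Evoked Cortical Potentials and Therapeutic-Window
    Modelling for Deep Brain Stimulation
Version: 0.1.0
Authors@R:
    person("dbsep", "developers", email = "dbsep@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing cortical evoked potentials recorded with
    scalp EEG during low-frequency subthalamic deep brain stimulation
    (DBS). Provides a synthetic-cohort generator (directional-lead
    geometry, stimulation-artifact and evoked-response simulation,
    monopolar-review outcomes), a preprocessing chain (trigger detection,
    epoching, baseline correction, template-subtraction artifact removal,
    zero-phase Butterworth band separation), short- and long-latency peak
    extraction with a per-hemisphere stimulation-intensity screen, a
    point-source electric-field model with binary-mask overlap scoring,
    and hemisphere-random-intercept linear mixed models of therapeutic
    window outcomes compared by AIC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
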