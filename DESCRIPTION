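Package: dreamlink
Title: Simulated Two-Way Communication with Lucid Dreamers in REM Sleep
Version: 0.1.0
Authors@R:
    person("Dreamlink", "Developers", email = "dreamlink@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully synthetic pipeline for experiments in which
    an experimenter poses questions to a sleeping, lucid-dreaming participant
    and the participant answers with volitional eye movements or facial
    muscle contractions. Provides Morse and left-right eye-movement answer
    codecs with protocol timing, per-team stimulus schedulers (targeted
    lucidity reactivation cueing, Morse-coded night protocol, blocked word
    stimulation), a polysomnography simulator with ground-truth embedded
    answer signals and simulated sleep scorers and signal raters, automated
    eye-movement and muscle-burst detection, multi-rater consensus trial
    classification under REM gating, and aggregate outcome and chance-level
    analyses (Fleiss' kappa, Fisher exact tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
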