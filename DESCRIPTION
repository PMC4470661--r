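Package: fetalmotion
Title: Automated Detection of Gross Fetal Movement from Overnight
    Two-Channel Accelerometry
Version: 0.1.0
Authors@R: person("Fetal Motion", "Maintainers", email = "fetalmotion@example.org",
    role = c("aut", "cre"))
Description: Detects gross fetal movements in overnight two-channel
    (fetal-abdomen / maternal-thigh) accelerometer recordings. Implements
    band-limiting and notch preprocessing, 50-ms rectified-integral burst
    detection with a 200 percent adaptive threshold plus fixed channel
    minima, rejection of maternal-movement, periodic-limb-movement,
    wake/restroom and fetal-hiccup artifacts, inter-event-interval
    histogram diagnostics, 10-s epoch agreement statistics (PABAK, Cohen's
    kappa), per-hour movement summaries, repeated-measures ANOVA with
    Scheffe post-hoc contrasts, and a ground-truth-labeled synthetic
    recording generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
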