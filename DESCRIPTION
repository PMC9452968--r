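Package: cholspeed
Title: Temporal Dynamics of Cholinergic Population Activity and Movement Speed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing dual-channel fiber-photometry recordings of
    cholinergic population activity together with pose-tracked movement speed in
    freely behaving mice. Implements isosbestic (405 nm) control correction of
    jGCaMP7s traces into frame-aligned z-scored dF/F, neck-speed kinematics with
    a stationary-session filter, speed tuning curves with saturating-exponential
    and log-linear fits, moving-average integration-window scans, multi-trial
    bivariate Granger causality built from first principles, and the
    linear mixed-effects models relating cholinergic activity to the logarithm
    of movement speed, lighting condition, and behavioral state. A synthetic-data
    generator emulates the recording conditions (semi-Markov open-field behavior,
    calcium-indicator kinetics, photobleaching, shared motion artifacts) with
    known ground truth for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
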