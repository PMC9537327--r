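Package: fatiguelag
Title: Simulation and Analysis of Perceived Muscle Fatigue Under Temporally
    Shifted Visual Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how temporal lags in online visual feedback of
    self-movement modulate the perception of muscle fatigue during paced cyclic
    finger movements. Provides a synthetic-experiment generator (cyclic
    kinematics with period jitter, fatiguing surface EMG, two-alternative
    forced-choice responses drawn from probit mixed models with known ground
    truth), an online cyclic-motion predictor that renders negatively lagged
    (preceding) visual feedback with a prediction-quality state variable and
    cross-correlation validation, EMG median-frequency fatigue spectroscopy and
    kinematic movement indices, probit generalized linear mixed models fitted
    by Laplace-approximated maximum likelihood with AIC model comparison, a
    repeated-measures inferential-statistics layer (t tests with Cohen's d,
    Holm adjustment, two-way within-subject ANOVA with partial eta squared,
    noncentral-t power analysis), and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
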