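# fatiguelag

Simulation and analysis toolkit for psychophysics experiments on how
temporal lags in online visual feedback of self-movement modulate the
perceived intensity of muscle fatigue.

In the paradigm this package serves, a participant paces cyclic finger
flexion at 2.14 Hz while watching a hand avatar whose motion is either
delayed (positive lag) or — by predicting the cyclic movement online —
displayed *ahead* of the hand (negative lag). On each trial the participant
reports in which of two intervals they felt more fatigued (2AFC); a
separate session measures delay detection with the same design. The
scientific question is whether the sensory prediction error injected by the
lag is attributed to the body's fatigue state, raising perceived fatigue
under delay and lowering it under preceding feedback.

The package is aimed at researchers in sensorimotor psychophysics and
motor-control biostatistics who want a fully testable, self-contained
implementation of this pipeline: because the paradigm's human data are not
publicly deposited, every stage runs against synthetic experiments with
known ground truth.

## What's inside

* **Synthetic experiments** — cohorts with participant-specific
  psychometric and physiological parameters; jittered raised-cosine
  kinematics at 500 Hz (60 Hz display track); surface-EMG emulation whose
  spectral median frequency declines with accumulating fatigue; full trial
  schedules of both experimental designs; Bernoulli 2AFC choices drawn
  from probit mixed models (`exp_config()`, `make_cohort()`,
  `build_dataset()`, `simulate_block()`).
* **Online cyclic-motion predictor** — adaptive phase/frequency tracking
  with harmonic coefficients, causal rendering of signed lags including
  phase-extrapolated *preceding* feedback, a prediction-quality variable
  `omega` in [0, 1] with 0.05-threshold trial gating, and
  cross-correlation validation with sub-sample peak refinement
  (`predictor_step()`, `render_lagged_feedback()`, `validate_lag()`,
  `gate_by_quality()`).
* **Signal metrics** — zero-phase 20–240 Hz Butterworth EMG preprocessing,
  Welch-based EMG median frequency, per-cycle movement amplitude /
  velocity / interval, and the baseline-normalized condition difference
  ΔI = (I_comparison − I_standard) / I_baseline (`emg_preprocess()`,
  `median_frequency()`, `cycle_metrics()`, `delta_index()`).
* **Psychometric mixed models** — the probability that participant *i*
  chooses the comparison interval at lag *x* is modeled as

  P_i(x) = Φ(α + α_i + (β + β_i)·x)                        (model 1)

  with probit link and independent Gaussian random effects; model 2 uses
  the participant's delay-detection probability P^d_i(x) as the predictor
  and model 3 uses both. Fitting maximizes the Laplace-approximated
  marginal likelihood; models are compared by AIC = −2·logL + 2k
  (`fit_probit_glmm()`, `model_comparison_aic()`, `slope_correlation()`).
* **Inferential statistics** — t tests with Cohen's d, Holm adjustment,
  two-way repeated-measures ANOVA with partial η², and noncentral-t power
  analysis (`t_tests()`, `holm_adjust()`, `rm_anova_2way()`, `power_t()`,
  `sample_size_t()`).
* **Pipeline** — one-call orchestration from a JSON config with strict
  CSV/JSON schemas and an md5 provenance manifest (`run_pipeline()`), plus
  a thin command-line wrapper in `inst/scripts/run_pipeline.R`.

## Worked example

Validate the preceding-feedback renderer at −33 ms on jittered synthetic
movement, and reproduce the planning computation:

```r
library(fatiguelag)

s <- predictor_validation_sim(n_trials = 20, lag_ms = -33, seed = 42)
sprintf("mean peak r = %.4f, mean lag = %.1f ms, retained %d/20",
        s$mean_peak, s$mean_lag_ms, s$n_retained)
#> "mean peak r = 0.9995, mean lag = -32.7 ms, retained 20/20"

sample_size_t(d = 1.00, alpha = 0.05, power = 0.8)
#> [1] 10
```

The peak normalized cross-correlation near 1 says the rendered feedback is
an almost perfect copy of the movement, and the recovered lag near −33 ms
says it genuinely runs ahead of the hand by the nominal amount; trials
whose prediction quality dipped below 0.05 would have been excluded (none
here). The sample-size line is the standard one-sample t-test computation
at Cohen's d = 1.

A full synthetic experiment, end to end:

```r
cfg <- system.file("extdata", "exp1_small.json", package = "fatiguelag")
res <- run_pipeline(cfg, outdir = "pipe_demo")
writeLines(res$report)
#> Experiment 1 synthetic run: 4 participants
#>
#> Fatigue-session choice probability by lag (mean +/- se):
#>     +0 ms: 0.500 +/- 0.096
#>    +50 ms: 0.646 +/- 0.092
#>    +83 ms: 0.708 +/- 0.087
#>
#> Negative-lag trials excluded by quality gate: 0.0%
#>
#> Model comparison (AIC):
#>   model 1: AIC 159.1 (delta 0.0)  <- best
#>   model 2: AIC 160.6 (delta 1.5)
#>   model 3: AIC 165.1 (delta 6.0)
#> ...
```

Choice probability rises with the imposed delay (the generating slope is
positive), and the AIC ranking recovers the generating model (model 1).
The output directory holds `trials.csv`, `fits.json`, `slopes.csv`,
`stats_report.json`, `report.txt` and an md5 `manifest.json`; identical
config + seed reproduce identical tables.

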