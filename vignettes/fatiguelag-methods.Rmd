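---
title: "Models and methods behind fatiguelag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fatiguelag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatiguelag)
```

## The scientific setting

During sustained cyclic movement, the brain continuously compares the
predicted sensory consequences of its motor commands with the feedback it
actually receives. `fatiguelag` packages the computational machinery for a
psychophysical paradigm that probes whether this prediction error feeds into
the *perceived intensity of muscle fatigue*: a participant paces finger
flexion/extension at 2.14 Hz between two target lines while watching a hand
avatar whose motion can be delayed (positive lag) or — using online
prediction of the cyclic movement — displayed *ahead* of the hand (negative
lag). On every trial the participant judges in which of two intervals they
felt more fatigued (two-alternative forced choice, 2AFC), and in a separate
session, in which interval the feedback was more asynchronous.

Because no public dataset exists for this paradigm, the package treats the
*synthetic experiment* as a first-class object: every analysis stage can be
exercised against data with known ground truth, and every headline quantity
(prediction quality of the negative-lag renderer, psychometric parameter
recovery, statistical calibration) is recomputed from scratch at run time.

## The synthetic experiment

### Kinematics

Flexion angle is a raised cosine per movement cycle,
$\theta(t) = c - \tfrac{s}{2}\cos\phi(t)$, with span $s$ drawn per
participant from the 38°–55° range used to individualize fatigue levels.
The waveform shape is a modeling choice (the paradigm specifies only paced
flexion between target lines); a raised cosine is smooth, periodic and
differentiable, which is what the downstream cycle metrics and the harmonic
predictor need, and — being a single harmonic — makes the periodic-limit
exactness of the predictor testable.

Cycle periods are multiplicatively jittered: lognormal with mean $1/2.14$ s
and coefficient of variation 3% by default. Paced human movement keeps
long-run tempo while wobbling cycle to cycle; 3% makes the prediction
problem nontrivial (phase drifts by ~0.19 rad per cycle RMS) without being
pathological for a metronome-paced task. Phase advances linearly within
each cycle, so realized periods are exactly recoverable by the cycle
metrics — several tests exploit that.

During the comparison phase of a trial the target span is reduced by the
small fractions used in the two designs (3.6% at +50 ms and 6% at +83 ms in
experiment 1; 2.4% at ±50 ms and 1.6% at ±33 ms in experiment 2), so
feedback-driven amplitude changes cannot masquerade as fatigue effects.

### Surface EMG

The paradigm analyses EMG only spectrally (median frequency as a fatigue
index) and in amplitude (average rectified value), so the generator produces
the simplest signal with controllable versions of exactly those properties:
Gaussian noise shaped in the frequency domain by a lognormal power profile.
The profile's spectral median is the configured target; its log-bandwidth
(0.35 by default) keeps essentially all mass inside the 20–240 Hz analysis
band, so the measured median lands within ±3 Hz of the target — an invariant
the tests enforce via the package's own `median_frequency()` oracle on long
traces. The initial median sits near 110 Hz (surface EMG medians typically
fall below ~120 Hz) and declines linearly with the block index at a
per-participant rate (`mf0 - decline * block`), emulating accumulating
fatigue. Channels are amplitude-gated by movement phase — flexor active
while flexing, extensor while extending — which modulates amplitude at
~2 Hz and leaves the spectral median essentially untouched. Absolute EMG
scale is arbitrary (no physical units are claimed anywhere downstream).

### Choices

2AFC responses are Bernoulli draws from probit mixed models. Under the
default generating model the probability of choosing the comparison
interval of a trial with lag $x$ (ms) for participant $i$ is
$$P_i(x) = \Phi\big(\alpha + \alpha_i + (\beta + \beta_i)\,x\big),$$
with independent Gaussian random effects $\alpha_i, \beta_i$. Two
alternative generators route the fatigue choice through the participant's
delay-*detection* probability $P^d_i(x)$ (alone, or together with $x$),
enabling model-recovery studies. Delay-session choices use $|x|$ in the
linear predictor: the delay judgment is about the magnitude of asynchrony,
which grows in both lag directions, giving the characteristic V-shape
around zero lag.

Defaults place the population fatigue-choice probability near 0.61 at
+50 ms (slope 0.0055 per ms) and delay detection near 0.82 at 50 ms —
a regime in which delay is discriminated more sharply than fatigue is
modulated, and chance-level behaviour at 0 ms. Every simulated trial
stores the exact probability used, so the Bernoulli parameters can be
audited against `choice_probability()` bit for bit.

### Seeding

All randomness flows from one master seed; sub-streams are derived by
hashing the seed with a string key (participant, block, purpose), so any
single block or trial can be regenerated in isolation and whole datasets
are byte-reproducible.

## The online cyclic-movement predictor

Rendering *preceding* feedback requires extrapolating the movement ahead of
the hand in real time. The reference apparatus used a published prediction
technique for human cyclic motion whose details live outside the main
literature; the predictor here is therefore a functional re-design that is
held to the same observable standards — peak cross-correlation of the
rendered track against the actual trajectory, the recovered lag, and a
quality variable that gates unreliable trials.

The movement is modeled as a truncated Fourier series in an internal phase,
$$\hat\theta = a_0 + \sum_{k=1}^{K} a_k \cos k\phi + b_k \sin k\phi,
\qquad K = 4,$$
with three interlocking adaptations per 500 Hz sample:

* **Phase/frequency tracking.** A second-order phase-locked loop driven by
  the normalized product of the one-step prediction error and the
  waveform's phase sensitivity $\partial\hat\theta/\partial\phi$
  (proportional gain 0.06 rad per normalized unit, integral gain 0.0012 Hz
  per sample, correction clamped to ±0.5 to survive glitches). The
  integral term makes the frequency estimate unbiased under zero-mean
  period jitter, which is what keeps the *mean* recovered lag centred on
  the nominal one.
* **Harmonic coefficients.** Normalized least-mean-squares on the Fourier
  basis (step 0.01), slow relative to the phase loop so the coefficient
  rotation cannot absorb phase errors.
* **Quality.** $\omega_t = \max(0, 1 - \bar e_t)$, where $\bar e_t$ is the
  squared one-step error normalized by *half* the running signal variance,
  exponentially smoothed with a 1 s time constant (variance tracked with a
  2 s constant). The half-variance normalization makes the statistic
  decisive: an uninformative prediction at the signal mean scores
  $\bar e \approx 2$ (so $\omega_t = 0$), a locked tracker scores
  $\ll 1$. A mid-cycle freeze of the input drives $\omega_t$ below the
  0.05 exclusion threshold in under 2 s; white noise pins it at 0.

The tracker bootstraps from a 2 s buffer (≥ 4 movement cycles at 2.14 Hz):
base frequency from the zero-padded spectrum with parabolic peak
refinement, coefficients by least squares, after which all processing is
strictly causal — a property the tests verify by corrupting future samples
and checking the rendered past is bit-identical.

Rendering: positive lags replay the buffered past (local linear
interpolation onto the 60 Hz display clock, preserving causality); zero lag
is a pass-through; negative lags evaluate the harmonic model at
$\phi + 2\pi f\,|{\rm lag}|$. Validation interpolates the display track
back onto the 500 Hz grid, scans the normalized cross-correlation over
±250 ms of integer lags, and refines the peak by parabolic interpolation —
the scan is checked against a brute-force oracle.

At the study's conditions (2.14 Hz, 3% jitter, 9-s test windows) the
renderer achieves mean peak correlations above 0.99 at both −33 and −50 ms
with mean recovered lags within 1 ms of nominal; the acceptance script
recomputes these numbers on every run. Exclusion fractions are ~0 here
because the synthetic movement lacks the occasional gross disruptions of
real participants (rests, tempo breaks, marker dropout) that produced the
reference exclusion rates; the gate's *mechanics* are instead exercised by
constructed freeze/noise cases.

## Signal metrics

* **EMG preprocessing** — 4th-order Butterworth band-pass 20–240 Hz then
  full-wave rectification. Filtering is zero-phase (forward–backward):
  the analysis is offline, and phase distortion would bias the
  phase-windowed ARV.
* **Median frequency** — Welch PSD (2 s Hann windows, 50% overlap) of the
  band-passed (not rectified) signal, cumulative in-band power inverted by
  linear interpolation. The reported value is the midpoint of the 49.9%
  and 50.1% power quantiles: identical to the usual median for continuous
  spectra, but well-defined when the cumulative power plateaus at one half
  (two equal-power lines yield the plateau midpoint). Windows must contain
  ≥ 2 s of signal; the 0.5 Hz bin width bounds the tone-recovery error.
* **Cycle metrics** — amplitude as mean per-cycle (max − min), cycles
  delimited by flexion-direction crossings of the target-line center
  located by linear interpolation (ties broken toward the earlier sample);
  interval as mean crossing spacing; velocity as mean |dθ/dt|.
* **Normalized change** — $\Delta I = (I_{\rm comparison} -
  I_{\rm standard}) / I_{\rm baseline}$ with the participant baseline taken
  from preparation periods displaying synchronous feedback (in the
  experiment-1 design, trials with the delay in phase 1 carry the delay
  through their preparation period and are excluded from the baseline).

## Psychometric mixed models

The three probit GLMMs are fitted by maximizing the Laplace-approximated
marginal likelihood — the inner problem (per-participant random-effect
modes) solved by damped Newton iterations with warm starts, the outer
problem (fixed effects and log-SDs) by L-BFGS-B started from the ordinary
probit fit. Random effects are independent Gaussians: the model equations
introduce the bias and slope deviations separately with no correlation
parameter, and the diagonal structure keeps all three models nested in the
same machinery (the correlated extension would add covariance parameters to
$k$ without changing any interface).

Numerical choices worth knowing:

* Predictors are scaled internally (lag per 100 ms; $P^d$ centered at 0.5)
  so the optimizer works on O(1) quantities; estimates, SEs (delta method)
  and posterior-mode deviations are reported back on the natural per-ms
  scale. The likelihood is invariant to this reparameterization, a
  property the tests check by rescaling ms to seconds.
* $P^d_i(x)$ is the participant's empirical delay-session proportion at
  lag $x$, pooled over presentation phases, with a $0.5/n$ continuity
  adjustment at proportions of exactly 0 or 1 so the probit linear
  predictor stays finite.
* Linear predictors are clamped to ±8 and Mills ratios computed on the log
  scale; log-SDs are bounded in $[\log 10^{-4}, \log 20]$, which lets a
  zero-variance truth collapse the fit onto the plain probit solution
  (matched to $10^{-3}$ on the linear predictor in the tests).
* AIC counts fixed effects plus variance components: $k = 4$ for models 1
  and 2, $k = 7$ for model 3. Model 3 carries two random intercepts whose
  individual variances are only weakly identified (their sum is what the
  likelihood sees); this costs it AIC but never destabilizes the ranking.
* The Laplace approximation is validated against an adaptive Gauss–Hermite
  quadrature oracle (31 nodes per dimension, coded independently in the
  test helpers) to within 0.1 log-likelihood units on all small instances,
  and against `lme4::glmer`'s probit Laplace fit on a moderate one.

Participant-level sensitivities $\beta + \beta_i$ feed a Pearson
correlation across tasks, mirroring the question of whether participants
who detect delay well also report more fatigue.

## Inferential statistics

One-sample/paired t statistics, Cohen's d, Holm's step-down adjustment, the
fully within-subject two-way ANOVA (each effect against its own
subject-by-effect stratum, partial $\eta^2 = SS_e/(SS_e+SS_{err})$, SS
closure checked to $10^{-10}$ on every call) and noncentral-t power are all
computed from their defining formulas, with base `p.adjust`, `t.test` and
`aov(... Error(...))` reserved as independent oracles in the tests. Holm is
the default multiplicity correction (with plain Bonferroni behind a flag),
and no sphericity correction is applied by default — the reference analyses
report uncorrected within-subject degrees of freedom; a design with
suspected sphericity violations should use few-level factors or external
corrections. The planning computation reads the conventional way: d = 1.00
at $\alpha = 0.05$ and power 0.8 for a two-sided one-sample test gives a
minimal n of 10 (the "$\beta = 0.8$" phrasing in such method sections
denotes power, not the type-II rate, which the n = 10 anchor confirms).

## Problem sizes and run times

The validation studies bundled with the package use: 110 trials per
negative-lag condition for the renderer (9-s test windows, ≥100 retained
after gating); 50 replicate experiments at the full design scale
(14 participants × 150 trials, plus a 120-trial delay session) for AIC
model recovery; 100 replicates for slope recovery and CI calibration; and
$10^4$–$10^5$ Monte-Carlo replicates for the statistical calibrations.
These sizes give the stochastic checks comfortable margins (e.g. binomial
SE ~0.006 on a 0.05 rejection rate at $10^4$ replicates) while the whole
suite stays desk-scale.

## What passing tests do and do not show

The generator produces stationary, well-behaved movement and EMG: no rests,
no tempo breaks, no electrode artifacts, no amplitude drift, no learning or
adaptation across blocks, and fatigue enters only as a spectral median
shift. Passing the suite therefore demonstrates the *correctness of the
machinery* — schedules, prediction, rendering, spectral estimation, mixed
-model likelihoods, statistical procedures — under known ground truth, not
that real participants behave like the generator. In particular, real
negative-lag exclusion rates, real AIC values and real F/t statistics
depend on human variability that is deliberately not imitated here.
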