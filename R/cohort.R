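#' Hyperparameters of the simulated cohort
#'
#' Population-level parameters from which participant-specific effects are
#' drawn. Psychometric effects follow the probit mixed models: the probability
#' of choosing the comparison interval is `pnorm(alpha + alpha_i +
#' (beta + beta_i) * x)` with `x` the comparison lag in ms, and the
#' delay-detection session has its own bias/slope pair. Random effects are
#' independent Gaussians across participants.
#'
#' Defaults place the population fatigue-choice probability near 0.61 at
#' +50 ms lag and the delay-detection probability near 0.82 at +50 ms,
#' i.e. delay is discriminated more sharply than fatigue is modulated, with
#' moderate between-participant spread. EMG parameters put the initial median
#' frequency near 110 Hz (surface EMG median frequencies typically sit below
#' ~120 Hz) with a gentle decline per block as fatigue accumulates.
#'
#' @param alpha,beta fixed-effect bias and slope (per ms) of the fatigue task.
#' @param sd_alpha,sd_beta SDs of the participant bias/slope deviations.
#' @param alpha_delay,beta_delay fixed effects of the delay-detection task.
#' @param sd_alpha_delay,sd_beta_delay their random-effect SDs.
#' @param slope_cor correlation between a participant's fatigue and delay
#'   slope deviations (0 by default; set nonzero for correlation-recovery
#'   studies).
#' @param beta_pd,sd_beta_pd fixed effect and random-effect SD of the slope on
#'   the (centered) delay-detection probability, used only when the fatigue
#'   task is generated under model 2 or 3.
#' @param amplitude_range degrees, range of per-participant target span.
#' @param mf0_mean,mf0_sd initial EMG median frequency (Hz) hyperdistribution.
#' @param mf_decline_mean,mf_decline_sd decline of the EMG median frequency
#'   per block (Hz/block, >= 0) hyperdistribution (truncated at 0).
#' @param emg_log_bw log-domain spectral bandwidth of the EMG power profile.
#' @return A list of class `fl_hyper`.
#' @export
cohort_hyper <- function(alpha = 0, beta = 0.0055,
                         sd_alpha = 0.15, sd_beta = 0.0025,
                         alpha_delay = 0, beta_delay = 0.018,
                         sd_alpha_delay = 0.2, sd_beta_delay = 0.006,
                         slope_cor = 0,
                         beta_pd = 1.0, sd_beta_pd = 0.3,
                         amplitude_range = c(38, 55),
                         mf0_mean = 110, mf0_sd = 5,
                         mf_decline_mean = 0.8, mf_decline_sd = 0.3,
                         emg_log_bw = 0.35) {
  fl_assert(all(c(sd_alpha, sd_beta, sd_alpha_delay, sd_beta_delay,
                  sd_beta_pd) >= 0),
            "fl_parameter_error", "random-effect SDs must be >= 0")
  fl_assert(abs(slope_cor) <= 1, "fl_parameter_error",
            "slope_cor must lie in [-1, 1]")
  structure(as.list(environment()), class = "fl_hyper")
}

#' Draw a synthetic cohort with known ground truth
#'
#' Samples participant-specific psychometric deviations, movement amplitudes
#' and EMG fatigue parameters from the hyperdistributions, and packages the
#' generating model so every downstream choice probability can be recomputed
#' exactly.
#'
#' @param config an [exp_config()] object.
#' @param hyper a [cohort_hyper()] object.
#' @param seed integer seed (default: the config's `rng_seed`).
#' @param model generating model for the fatigue task: 1 (lag drives choice,
#'   the default), 2 (delay-detection probability drives choice) or 3 (both).
#' @return A list with `participants` (data frame, one row per participant)
#'   and `truth` (class `fl_truth`: generating model id, fixed effects,
#'   random-effect SDs and the per-participant realized effects).
#' @examples
#' cohort <- make_cohort(exp_config(1, n_participants = 4), seed = 7)
#' cohort$participants[, c("id", "alpha_i", "beta_i", "amplitude_deg")]
#' @export
make_cohort <- function(config, hyper = cohort_hyper(), seed = config$rng_seed,
                        model = 1) {
  fl_assert(inherits(hyper, "fl_hyper"), "fl_parameter_error",
            "hyper must be a cohort_hyper() object")
  fl_assert(model %in% 1:3, "fl_parameter_error", "model must be 1, 2 or 3")
  n <- config$n_participants
  p <- with_seed(substream_seed(seed, "cohort"), {
    # fatigue/delay slope deviations may be correlated (slope_cor)
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    zd <- hyper$slope_cor * z1 + sqrt(1 - hyper$slope_cor^2) * z2
    data.frame(
      id = sprintf("P%02d", seq_len(n)),
      alpha_i = stats::rnorm(n, 0, hyper$sd_alpha),
      beta_i = hyper$sd_beta * z1,
      alpha_d_i = stats::rnorm(n, 0, hyper$sd_alpha_delay),
      beta_d_i = hyper$sd_beta_delay * zd,
      beta_pd_i = stats::rnorm(n, 0, hyper$sd_beta_pd),
      amplitude_deg = stats::runif(n, hyper$amplitude_range[1],
                                   hyper$amplitude_range[2]),
      jitter_cv = config$jitter_cv,
      mf0_hz = pmax(60, stats::rnorm(n, hyper$mf0_mean, hyper$mf0_sd)),
      mf_decline = pmax(0, stats::rnorm(n, hyper$mf_decline_mean,
                                        hyper$mf_decline_sd)),
      emg_log_bw = hyper$emg_log_bw,
      stringsAsFactors = FALSE
    )
  })
  truth <- structure(list(
    model = as.integer(model),
    alpha = hyper$alpha, beta = hyper$beta,
    alpha_delay = hyper$alpha_delay, beta_delay = hyper$beta_delay,
    beta_pd = hyper$beta_pd,
    sd_alpha = hyper$sd_alpha, sd_beta = hyper$sd_beta,
    sd_alpha_delay = hyper$sd_alpha_delay, sd_beta_delay = hyper$sd_beta_delay,
    sd_beta_pd = hyper$sd_beta_pd,
    participants = p[, c("id", "alpha_i", "beta_i", "alpha_d_i", "beta_d_i",
                         "beta_pd_i")]
  ), class = "fl_truth")
  list(participants = p, truth = truth)
}
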