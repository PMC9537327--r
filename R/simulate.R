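#' Generate jittered movement cycles
#'
#' Cycle periods are drawn from a lognormal distribution whose mean is the
#' reciprocal of the paced frequency and whose coefficient of variation is
#' `cv` (multiplicative jitter; paced movement keeps long-run tempo but
#' wobbles cycle by cycle). The instantaneous phase advances linearly within
#' each cycle, so the flexion angle is a raised cosine per cycle:
#' `angle = center - span/2 * cos(phase)`.
#'
#' @param duration seconds of movement to generate.
#' @param f0 paced frequency in Hz.
#' @param cv coefficient of variation of the cycle period (>= 0).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @return List with `t` (time, s), `phase` (rad, unwrapped), `periods`
#'   (realized cycle periods, s).
#' @export
generate_cycles <- function(duration, f0, cv = 0.03, fs = 500, seed = 1L) {
  fl_assert(cv >= 0, "fl_parameter_error", "jitter cv must be >= 0")
  fl_assert(duration > 0 && f0 > 0, "fl_parameter_error",
            "duration and f0 must be positive")
  mean_period <- 1 / f0
  n_cycles <- ceiling(duration / mean_period * (1 + 5 * cv)) + 4
  periods <- with_seed(seed, {
    if (cv == 0) rep(mean_period, n_cycles)
    else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n_cycles, meanlog = log(mean_period) - sdlog^2 / 2,
                    sdlog = sdlog)
    }
  })
  ends <- cumsum(periods)
  keep <- seq_len(which(ends >= duration)[1])
  periods <- periods[keep]
  starts <- c(0, cumsum(periods))[seq_along(periods)]
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  idx <- findInterval(t, starts)
  phase <- 2 * pi * (idx - 1) + 2 * pi * (t - starts[idx]) / periods[idx]
  list(t = t, phase = phase, periods = periods)
}

# Lognormal-profile spectral shaping of white Gaussian noise: power spectrum
# proportional to dlnorm(f, log(mf), log_bw), so the spectral median of the
# (untruncated) profile is mf.
shape_emg_noise <- function(n, fs, mf, log_bw, seed) {
  x <- with_seed(seed, stats::rnorm(n))
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f_fold <- pmin(f, fs - f)                    # two-sided spectrum
  mag <- sqrt(stats::dlnorm(pmax(f_fold, 1e-6), log(mf), log_bw))
  y <- Re(stats::fft(X * mag, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Simulate one experimental block
#'
#' Generates the continuous finger-flexion trace (500 Hz), two-channel surface
#' EMG, the 60 Hz display track and per-trial window metadata for one block of
#' seamless cyclic movement. Within the comparison phase of each trial the
#' target span is reduced by the configured fraction for that lag. The EMG is
#' band-shaped Gaussian noise whose spectral median frequency declines with
#' the cumulative fatigue state (`mf0 - mf_decline * block`), amplitude-gated
#' by movement phase: the flexor channel is active while flexing
#' (`sin(phase) > 0`), the extensor while extending.
#'
#' @param participant one row of the cohort `participants` data frame.
#' @param config an [exp_config()] object.
#' @param block block index (1-based; drives the fatigue state).
#' @param lag_schedule data frame from [block_schedule()].
#' @param seed integer seed.
#' @return A list of class `fl_block`: `kin` (t, angle_deg at 500 Hz),
#'   `emg` (t, flexor, extensor), `display` (t, angle_deg at 60 Hz),
#'   `windows` (per-trial window bounds), `periods` (realized cycle periods),
#'   `mf_target` (Hz).
#' @export
simulate_block <- function(participant, config, block, lag_schedule,
                           seed = config$rng_seed) {
  n_trials <- nrow(lag_schedule)
  trial_dur <- trial_duration(config)
  expected <- if (identical(n_trials, config$delay_trials_per_block) ||
                  identical(n_trials, config$trials_per_block)) TRUE else FALSE
  fl_assert(expected, "fl_schedule_error",
            "lag_schedule has %d trials; config expects %d (or %d for delay sessions)",
            n_trials, config$trials_per_block, config$delay_trials_per_block)
  duration <- n_trials * trial_dur
  fs <- config$capture_rate

  cyc <- generate_cycles(duration, config$movement_frequency,
                         participant$jitter_cv, fs,
                         seed = substream_seed(seed, participant$id, block, "kin"))
  t <- cyc$t

  lay <- config$trial_layout
  starts <- (lag_schedule$trial - 1) * trial_dur
  p1 <- cbind(starts + lay$preparation, starts + lay$preparation + 4)
  p2 <- cbind(starts + lay$preparation + 5, starts + lay$preparation + 9)
  windows <- data.frame(
    trial = lag_schedule$trial, lag_ms = lag_schedule$lag_ms,
    comparison_phase = lag_schedule$comparison_phase,
    sound = lag_schedule$sound,
    prep_start = starts, prep_end = starts + lay$preparation,
    phase1_start = p1[, 1], phase1_end = p1[, 2],
    phase2_start = p2[, 1], phase2_end = p2[, 2]
  )

  span <- rep(participant$amplitude_deg, length(t))
  for (i in seq_len(n_trials)) {
    red <- span_reduction_for(config, windows$lag_ms[i])
    if (red > 0) {
      w <- if (windows$comparison_phase[i] == 1) p1[i, ] else p2[i, ]
      span[t >= w[1] & t < w[2]] <- participant$amplitude_deg * (1 - red)
    }
  }
  angle <- span / 2 - span / 2 * cos(cyc$phase)

  mf_target <- max(40, participant$mf0_hz - participant$mf_decline * block)
  gate_flex <- 0.4 + 0.6 * pmax(0, sin(cyc$phase))
  gate_ext <- 0.4 + 0.6 * pmax(0, -sin(cyc$phase))
  emg_f <- shape_emg_noise(length(t), fs, mf_target, participant$emg_log_bw,
                           substream_seed(seed, participant$id, block, "emgf")) *
    gate_flex
  emg_e <- shape_emg_noise(length(t), fs, mf_target, participant$emg_log_bw,
                           substream_seed(seed, participant$id, block, "emge")) *
    gate_ext

  t_disp <- seq(0, max(t), by = 1 / config$display_rate)
  display <- data.frame(t = t_disp,
                        angle_deg = resample_series(t, angle, t_disp))

  structure(list(
    kin = data.frame(t = t, angle_deg = angle),
    emg = data.frame(t = t, flexor = emg_f, extensor = emg_e),
    display = display,
    windows = windows,
    periods = cyc$periods,
    mf_target = mf_target
  ), class = "fl_block")
}

#' Choice probability under the generating probit models
#'
#' Recomputes, from the stored ground truth, the exact Bernoulli parameter
#' used when simulating a choice. For the fatigue task: model 1 uses the lag
#' `x` (ms); model 2 uses the participant's (centered) delay-detection
#' probability `pd`; model 3 uses both. For the delay task the linear
#' predictor uses `|x|` (the judgment is about the magnitude of asynchrony,
#' which grows in both lag directions).
#'
#' @param truth an `fl_truth` object from [make_cohort()].
#' @param id participant id(s).
#' @param lag_ms signed lag(s), ms.
#' @param task "fatigue" or "delay".
#' @param pd delay-detection probability per row (required for fatigue task
#'   under models 2 and 3).
#' @return Vector of probabilities.
#' @export
choice_probability <- function(truth, id, lag_ms, task = "fatigue", pd = NULL) {
  pp <- truth$participants
  i <- match(id, pp$id)
  fl_assert(!anyNA(i), "fl_parameter_error", "unknown participant id")
  if (task == "delay") {
    eta <- truth$alpha_delay + pp$alpha_d_i[i] +
      (truth$beta_delay + pp$beta_d_i[i]) * abs(lag_ms)
    return(stats::pnorm(eta))
  }
  m <- truth$model
  if (m %in% c(2, 3)) {
    fl_assert(!is.null(pd), "fl_dependency_error",
              "model %d requires delay-task probabilities (pd)", m)
  }
  eta <- switch(as.character(m),
    "1" = truth$alpha + pp$alpha_i[i] + (truth$beta + pp$beta_i[i]) * lag_ms,
    "2" = truth$alpha + pp$alpha_d_i[i] +
      (truth$beta_pd + pp$beta_pd_i[i]) * (pd - 0.5),
    "3" = truth$alpha + pp$alpha_i[i] + pp$alpha_d_i[i] +
      (truth$beta + pp$beta_i[i]) * lag_ms +
      (truth$beta_pd + pp$beta_pd_i[i]) * (pd - 0.5))
  stats::pnorm(eta)
}

#' Simulate 2AFC choices for a trial table
#'
#' Draws binary "chose the comparison interval" responses from the generating
#' probit model, one Bernoulli draw per trial. The exact probability used is
#' returned in `p_true` so it can be audited against
#' [choice_probability()].
#'
#' @param trial_table data frame with columns `participant_id`, `lag_ms`,
#'   `comparison_phase` (and `pd` for fatigue generation under models 2/3).
#' @param truth `fl_truth` object.
#' @param task "fatigue" or "delay".
#' @param seed integer seed.
#' @return The trial table with added `p_true` and `choice_comparison`
#'   columns.
#' @export
simulate_choices <- function(trial_table, truth, task = c("fatigue", "delay"),
                             seed = 1L) {
  task <- match.arg(task)
  p <- choice_probability(truth, trial_table$participant_id,
                          trial_table$lag_ms, task, pd = trial_table$pd)
  trial_table$p_true <- p
  trial_table$choice_comparison <- with_seed(
    substream_seed(seed, task, "choices"),
    as.integer(stats::runif(nrow(trial_table)) < p))
  trial_table
}

#' Build a complete synthetic experiment
#'
#' Generates the full trial tables of the fatigue-evaluation session and the
#' delay-detection session for a whole cohort: per-block randomized schedules,
#' delay-session choices, the per-participant empirical delay-detection
#' probabilities (used as the `pd` predictor, with a 0.5/n continuity
#' adjustment at 0/1), and fatigue-session choices drawn from the generating
#' model stored in `truth`. Kinematic/EMG traces are generated on demand with
#' [simulate_block()] when `traces = TRUE` (they are bulky; schedules and
#' choices do not need them).
#'
#' @param config an [exp_config()] object.
#' @param cohort result of [make_cohort()].
#' @param seed master seed (default: config's).
#' @param traces logical: also simulate per-block kinematics and EMG.
#' @return A list of class `fl_dataset`: `trials` (fatigue session),
#'   `delay_trials`, `pd_table`, `config`, `cohort`, and `blocks` (list of
#'   `fl_block`, only if `traces`).
#' @examples
#' cfg <- exp_config(1, n_participants = 3, blocks_per_participant = 2,
#'                   delay_blocks = 2)
#' ds <- build_dataset(cfg, make_cohort(cfg, seed = 1), seed = 1)
#' table(ds$trials$lag_ms)
#' @export
build_dataset <- function(config, cohort, seed = config$rng_seed,
                          traces = FALSE) {
  parts <- cohort$participants
  truth <- cohort$truth

  expand_session <- function(session, n_blocks) {
    do.call(rbind, lapply(seq_len(nrow(parts)), function(i) {
      do.call(rbind, lapply(seq_len(n_blocks), function(b) {
        sch <- block_schedule(config, session,
                              seed = substream_seed(seed, parts$id[i], b,
                                                    session, "sched"))
        data.frame(participant_id = parts$id[i],
                   experiment = config$experiment_id,
                   session = session, block = b, sch,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  delay <- expand_session("delay", config$delay_blocks)
  delay <- simulate_choices(delay, truth, "delay",
                            seed = substream_seed(seed, "delay"))
  pd_table <- delay_probabilities(delay)

  fat <- expand_session("fatigue", config$blocks_per_participant)
  if (truth$model %in% c(2, 3)) {
    key <- paste(fat$participant_id, fat$lag_ms)
    fat$pd <- pd_table$pd[match(key, paste(pd_table$participant_id,
                                           pd_table$lag_ms))]
  }
  fat <- simulate_choices(fat, truth, "fatigue",
                          seed = substream_seed(seed, "fatigue"))

  for (nm in c("omega_min", "excluded")) {
    fat[[nm]] <- if (nm == "excluded") 0L else NA_real_
    delay[[nm]] <- if (nm == "excluded") 0L else NA_real_
  }

  blocks <- NULL
  if (traces) {
    blocks <- list()
    for (i in seq_len(nrow(parts))) {
      for (b in seq_len(config$blocks_per_participant)) {
        sch <- fat[fat$participant_id == parts$id[i] & fat$block == b,
                   c("trial", "lag_ms", "comparison_phase", "sound")]
        sch <- sch[order(sch$trial), ]
        blocks[[paste(parts$id[i], b, sep = "_")]] <-
          simulate_block(parts[i, ], config, b, sch, seed = seed)
      }
    }
  }

  structure(list(trials = fat, delay_trials = delay, pd_table = pd_table,
                 config = config, cohort = cohort, blocks = blocks),
            class = "fl_dataset")
}

#' Empirical delay-detection probabilities
#'
#' Per-participant proportion of "comparison judged more asynchronous"
#' responses at each signed lag, pooled over presentation phases, with a
#' 0.5/n continuity adjustment applied to proportions of exactly 0 or 1 so
#' they can sit inside a probit linear predictor.
#'
#' @param delay_records delay-session trial records with `choice_comparison`.
#' @return Data frame `participant_id`, `lag_ms`, `n`, `pd`.
#' @export
delay_probabilities <- function(delay_records) {
  agg <- stats::aggregate(
    choice_comparison ~ participant_id + lag_ms, data = delay_records,
    FUN = function(z) c(n = length(z), k = sum(z)))
  n <- agg$choice_comparison[, "n"]
  k <- agg$choice_comparison[, "k"]
  pd <- k / n
  pd[pd == 0] <- 0.5 / n[pd == 0]
  pd[pd == 1] <- 1 - 0.5 / n[pd == 1]
  data.frame(participant_id = agg$participant_id, lag_ms = agg$lag_ms,
             n = n, pd = pd, stringsAsFactors = FALSE)
}
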