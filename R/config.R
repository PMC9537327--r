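#' Experiment configuration
#'
#' Builds the configuration object describing one of the two experimental
#' designs: paced cyclic finger flexion at 2.14 Hz with a comparison lag
#' imposed on the visual feedback in one of the two phases of each trial's
#' test period.
#'
#' Experiment 1 uses positive lags only (0, +50, +83 ms), a sound-on/sound-off
#' manipulation of the pacing metronome during the test period, 19-s trials
#' (8 s preparation, 9 s test, 2 s response) and 10 trials per block.
#' Experiment 2 uses signed lags (-50, -33, 0, +33, +50 ms; the delay-judgment
#' session adds +/-17 ms), no sound factor, and 18-s trials (7 s preparation,
#' 9 s test, 2 s response). The span of the movement target lines is reduced
#' by a small fraction while the comparison lag is displayed (3.6% at +50 ms
#' and 6% at +83 ms in Experiment 1; 2.4% at +/-50 ms and 1.6% at +/-33 ms in
#' Experiment 2) so that feedback-driven amplitude changes do not confound the
#' fatigue judgment.
#'
#' @param experiment 1 or 2.
#' @param n_participants cohort size (default 14 per experiment).
#' @param blocks_per_participant number of blocks in the fatigue session
#'   (default 15).
#' @param delay_blocks number of blocks in the delay-detection session
#'   (default 12 for experiment 1, 10 for experiment 2).
#' @param movement_frequency paced movement frequency in Hz (default 2.14).
#' @param target_span_deg length-2 range (degrees) from which each
#'   participant's target span is drawn (default 38-55).
#' @param jitter_cv coefficient of variation of the multiplicative lognormal
#'   cycle-period jitter (default 0.03).
#' @param rng_seed integer master seed stored with the config.
#' @return An object of class `fl_config` (a list).
#' @examples
#' cfg <- exp_config(1, n_participants = 4, blocks_per_participant = 3)
#' cfg$lag_conditions
#' @export
exp_config <- function(experiment = 1,
                       n_participants = 14,
                       blocks_per_participant = 15,
                       delay_blocks = if (experiment == 1) 12 else 10,
                       movement_frequency = 2.14,
                       target_span_deg = c(38, 55),
                       jitter_cv = 0.03,
                       rng_seed = 1L) {
  fl_assert(experiment %in% c(1, 2), "fl_config_error",
            "experiment must be 1 or 2, got %s", format(experiment))
  fl_assert(is_count(n_participants), "fl_config_error",
            "n_participants: must be a positive integer")
  fl_assert(is_count(blocks_per_participant), "fl_config_error",
            "blocks_per_participant: must be a positive integer")
  fl_assert(movement_frequency > 0, "fl_config_error",
            "movement_frequency: must be positive")
  fl_assert(length(target_span_deg) == 2 && all(target_span_deg > 0) &&
              diff(target_span_deg) >= 0, "fl_config_error",
            "target_span_deg: must be an increasing positive range")
  fl_assert(jitter_cv >= 0, "fl_config_error", "jitter_cv: must be >= 0")

  if (experiment == 1) {
    lags <- c(0, 50, 83)
    delay_lags <- lags
    layout <- list(preparation = 8, test = 9, response = 2)
    sound_conditions <- c(0L, 1L)
    span_reduction <- c("50" = 0.036, "83" = 0.06)
  } else {
    lags <- c(-50, -33, 0, 33, 50)
    delay_lags <- c(-50, -33, -17, 0, 17, 33, 50)
    layout <- list(preparation = 7, test = 9, response = 2)
    sound_conditions <- 0L
    span_reduction <- c("33" = 0.016, "50" = 0.024)
    fl_assert(all(sort(lags) == sort(-lags)), "fl_config_error",
              "experiment 2 lag conditions must be symmetric around 0")
  }
  fl_assert(all(unlist(layout) > 0), "fl_config_error",
            "trial layout durations must all be positive")

  structure(list(
    experiment_id = as.integer(experiment),
    movement_frequency = movement_frequency,
    lag_conditions = lags,
    delay_lag_conditions = delay_lags,
    n_participants = as.integer(n_participants),
    blocks_per_participant = as.integer(blocks_per_participant),
    delay_blocks = as.integer(delay_blocks),
    trials_per_block = if (experiment == 1) 10L else 10L,
    delay_trials_per_block = if (experiment == 1) 10L else 14L,
    trial_layout = layout,
    sound_conditions = sound_conditions,
    target_span_deg = target_span_deg,
    span_reduction = span_reduction,
    jitter_cv = jitter_cv,
    capture_rate = 500,
    display_rate = 60,
    rng_seed = as.integer(rng_seed)
  ), class = "fl_config")
}

#' @export
print.fl_config <- function(x, ...) {
  cat(sprintf("Experiment %d config: %d participants, %d fatigue blocks (+%d delay blocks)\n",
              x$experiment_id, x$n_participants, x$blocks_per_participant,
              x$delay_blocks))
  cat(sprintf("  movement %.2f Hz, lags [%s] ms, %d trials/block\n",
              x$movement_frequency,
              paste(x$lag_conditions, collapse = ", "), x$trials_per_block))
  invisible(x)
}

trial_duration <- function(config) {
  sum(unlist(config$trial_layout))
}

span_reduction_for <- function(config, lag_ms) {
  key <- as.character(abs(lag_ms))
  r <- config$span_reduction[key]
  ifelse(is.na(r), 0, r)
}

#' Build the lag/phase/sound schedule for one block
#'
#' Enumerates the trial cells of one experimental block and randomizes their
#' order. In experiment 1 the ten trials are the five comparison cells
#' (+50 ms in phase 1 or 2, +83 ms in phase 1 or 2, 0 ms with a random phase
#' label) crossed with the two metronome conditions. In experiment 2 (fatigue
#' session) each signed lag appears once per phase; the delay session uses the
#' seven-lag set, again once per phase.
#'
#' @param config an [exp_config()] object.
#' @param session "fatigue" or "delay".
#' @param seed integer seed for order randomization.
#' @return A data frame with columns `trial`, `lag_ms`, `comparison_phase`,
#'   `sound`.
#' @export
block_schedule <- function(config, session = c("fatigue", "delay"), seed = 1L) {
  session <- match.arg(session)
  lags <- if (session == "delay") config$delay_lag_conditions else
    config$lag_conditions
  with_seed(seed, {
    if (config$experiment_id == 1) {
      nz <- setdiff(lags, 0)
      cells <- rbind(
        expand.grid(lag_ms = nz, comparison_phase = c(1L, 2L)),
        data.frame(lag_ms = 0, comparison_phase = sample(1:2, 1))
      )
      cells <- merge(cells, data.frame(sound = config$sound_conditions))
    } else {
      cells <- expand.grid(lag_ms = lags, comparison_phase = c(1L, 2L))
      cells$sound <- 0L
    }
    cells <- cells[sample(nrow(cells)), , drop = FALSE]
  })
  expected <- if (session == "delay") config$delay_trials_per_block else
    config$trials_per_block
  fl_assert(nrow(cells) == expected, "fl_schedule_error",
            "schedule enumerates %d cells but trials_per_block is %d",
            nrow(cells), expected)
  data.frame(trial = seq_len(nrow(cells)),
             lag_ms = cells$lag_ms,
             comparison_phase = as.integer(cells$comparison_phase),
             sound = as.integer(cells$sound),
             row.names = NULL)
}
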