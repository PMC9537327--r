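test_that("cohort generation is deterministic and respects hyperparameters", {
  cfg <- exp_config(1, n_participants = 6)
  c1 <- make_cohort(cfg, seed = 42)
  c2 <- make_cohort(cfg, seed = 42)
  expect_identical(c1, c2)
  c3 <- make_cohort(cfg, seed = 43)
  expect_false(identical(c1$participants, c3$participants))

  # degenerate variances: population curve only
  h0 <- cohort_hyper(sd_alpha = 0, sd_beta = 0, sd_alpha_delay = 0,
                     sd_beta_delay = 0, sd_beta_pd = 0)
  c0 <- make_cohort(cfg, h0, seed = 1)
  expect_true(all(c0$participants$alpha_i == 0))
  expect_true(all(c0$participants$beta_i == 0))

  expect_error(cohort_hyper(sd_beta = -1), class = "fl_parameter_error")
})

test_that("realized random-effect spread matches the hyperdistribution", {
  cfg <- exp_config(1, n_participants = 1000)
  co <- make_cohort(cfg, cohort_hyper(sd_beta = 0.5), seed = 7)
  s <- sd(co$participants$beta_i)
  expect_lt(abs(s - 0.5) / 0.5, 0.10)
})

test_that("amplitudes stay within the configured span", {
  cfg <- exp_config(2, n_participants = 50)
  co <- make_cohort(cfg, seed = 5)
  expect_true(all(co$participants$amplitude_deg >= 38 &
                    co$participants$amplitude_deg <= 55))
  expect_true(all(co$participants$jitter_cv >= 0))
  expect_true(all(co$participants$mf_decline >= 0))
})

test_that("jitter-free cycles have the exact paced period", {
  cyc <- generate_cycles(2, 2.14, cv = 0, fs = 500, seed = 1)
  expect_equal(unique(round(cyc$periods, 10)), 1 / 2.14)
  expect_equal(mean(diff(cyc$periods)), 0)
})

test_that("mean cycle frequency stays within 1% of the paced frequency", {
  for (seed in 1:3) {
    cyc <- generate_cycles(60, 2.14, cv = 0.05, fs = 500, seed = seed)
    expect_gte(length(cyc$periods), 100)
    f_real <- 1 / mean(cyc$periods)
    expect_lt(abs(f_real - 2.14) / 2.14, 0.01)
  }
})

test_that("simulated block kinematics follow span, schedule and fatigue state", {
  cfg <- exp_config(1, n_participants = 1, blocks_per_participant = 1)
  co <- make_cohort(cfg, seed = 2)
  part <- co$participants[1, ]
  sch <- block_schedule(cfg, "fatigue", seed = 3)
  blk <- simulate_block(part, cfg, block = 1, sch, seed = 4)
  expect_equal(nrow(blk$windows), 10)
  expect_equal(max(blk$kin$t) + 1 / 500, 10 * 19, tolerance = 1e-9)
  expect_equal(nrow(blk$display),
               length(seq(0, max(blk$kin$t), by = 1 / 60)))
  # raised cosine spans [0, amplitude] outside comparison windows
  expect_lt(max(blk$kin$angle_deg), part$amplitude_deg + 1e-6)
  expect_gt(min(blk$kin$angle_deg), -1e-6)
  # schedule mismatch is a schedule error
  expect_error(simulate_block(part, cfg, 1, sch[1:3, ], seed = 1),
               class = "fl_schedule_error")
})

test_that("generated EMG median frequency tracks its configured target", {
  cfg <- exp_config(1, n_participants = 1, blocks_per_participant = 1)
  co <- make_cohort(cfg, seed = 2)
  part <- co$participants[1, ]
  part$mf0_hz <- 110
  part$mf_decline <- 2
  sch <- block_schedule(cfg, "fatigue", seed = 3)
  # block 5 target: 110 - 2 * 5 = 100 Hz, recovered within +/-3 Hz
  blk5 <- simulate_block(part, cfg, block = 5, sch, seed = 6)
  mf <- median_frequency(blk5$emg$flexor, fs = 500)
  expect_lt(abs(mf - 100), 3)
})

test_that("zero fatigue drift leaves the EMG spectrum flat across blocks", {
  cfg <- exp_config(1, n_participants = 1, blocks_per_participant = 1)
  co <- make_cohort(cfg, seed = 2)
  part <- co$participants[1, ]
  part$mf0_hz <- 110
  part$mf_decline <- 0
  sch <- block_schedule(cfg, "fatigue", seed = 3)[1:2, ]  # short blocks
  cfg2 <- cfg; cfg2$trials_per_block <- 2L
  mfs <- vapply(1:20, function(b) {
    blk <- simulate_block(part, cfg2, block = b, sch, seed = 100 + b)
    median_frequency(blk$emg$flexor, fs = 500)
  }, numeric(1))
  fit <- lm(mfs ~ seq_along(mfs))
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("choice simulation reproduces its generating probabilities", {
  cfg <- exp_config(1, n_participants = 2)
  co <- make_cohort(cfg, seed = 8)
  tt <- data.frame(participant_id = rep(co$participants$id, each = 3),
                   lag_ms = rep(c(0, 50, 83), 2),
                   comparison_phase = 1L)
  rec <- simulate_choices(tt, co$truth, "fatigue", seed = 1)
  p_re <- choice_probability(co$truth, rec$participant_id, rec$lag_ms,
                             "fatigue")
  expect_identical(rec$p_true, p_re)
  expect_true(all(rec$choice_comparison %in% 0:1))
})

test_that("degenerate psychometric parameters give chance and saturation", {
  cfg <- exp_config(1, n_participants = 1)
  h <- cohort_hyper(alpha = 0, beta = 0, sd_alpha = 0, sd_beta = 0)
  co <- make_cohort(cfg, h, seed = 1)
  n <- 20000
  tt <- data.frame(participant_id = rep("P01", n), lag_ms = 50,
                   comparison_phase = 1L)
  rec <- simulate_choices(tt, co$truth, "fatigue", seed = 2)
  expect_true(all(rec$p_true == 0.5))
  expect_lt(abs(mean(rec$choice_comparison) - 0.5), 0.01)

  # saturation: enormous slope pins the choice at 1 for positive lag
  h2 <- cohort_hyper(alpha = 0, beta = 100, sd_alpha = 0, sd_beta = 0)
  co2 <- make_cohort(cfg, h2, seed = 1)
  rec2 <- simulate_choices(tt[1:100, ], co2$truth, "fatigue", seed = 3)
  expect_true(all(rec2$choice_comparison == 1L))
})

test_that("binomial sampling matches a 0.75 target rate", {
  # beta chosen so that pnorm(beta * 50) = 0.75
  beta <- qnorm(0.75) / 50
  cfg <- exp_config(1, n_participants = 1)
  h <- cohort_hyper(alpha = 0, beta = beta, sd_alpha = 0, sd_beta = 0)
  co <- make_cohort(cfg, h, seed = 1)
  tt <- data.frame(participant_id = rep("P01", 10000), lag_ms = 50,
                   comparison_phase = 1L)
  rec <- simulate_choices(tt, co$truth, "fatigue", seed = 4)
  expect_equal(rec$p_true[1], 0.75, tolerance = 1e-12)
  expect_lt(abs(mean(rec$choice_comparison) - 0.75), 0.01)
})

test_that("schedule marginals match both experimental designs", {
  # experiment 1: 15 blocks -> 150 trials, 75 sound-on, lag cells 30/60/60
  cfg1 <- exp_config(1, n_participants = 1, blocks_per_participant = 15,
                     delay_blocks = 1)
  ds1 <- build_dataset(cfg1, make_cohort(cfg1, seed = 1), seed = 1)
  expect_equal(nrow(ds1$trials), 150)
  expect_equal(sum(ds1$trials$sound), 75)
  expect_equal(as.vector(table(ds1$trials$lag_ms)), c(30, 60, 60))
  nz <- ds1$trials[ds1$trials$lag_ms > 0, ]
  expect_true(all(table(nz$lag_ms, nz$comparison_phase) == 30))

  # experiment 2: each signed lag 15x per phase; delay session 7 lags x 2
  cfg2 <- exp_config(2, n_participants = 1, blocks_per_participant = 15,
                     delay_blocks = 10)
  ds2 <- build_dataset(cfg2, make_cohort(cfg2, seed = 1), seed = 1)
  expect_true(all(table(ds2$trials$lag_ms, ds2$trials$comparison_phase) == 15))
  expect_equal(sort(unique(ds2$trials$lag_ms)), c(-50, -33, 0, 33, 50))
  expect_equal(sort(unique(ds2$delay_trials$lag_ms)),
               c(-50, -33, -17, 0, 17, 33, 50))
  expect_true(all(table(ds2$delay_trials$lag_ms,
                        ds2$delay_trials$comparison_phase) == 10))

  # determinism of the full dataset
  ds2b <- build_dataset(cfg2, make_cohort(cfg2, seed = 1), seed = 1)
  expect_identical(ds2$trials, ds2b$trials)
})
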