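sine_trace <- function(dur = 10, f = 2.14, fs = 500, amp = 20) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  list(t = t, angle = amp - amp * cos(2 * pi * f * t))
}

test_that("stationary periodic input is tracked to high precision", {
  tr <- sine_trace()
  run <- predictor_run(predictor_init(500), tr$angle)
  n <- length(tr$t)
  expect_lt(abs(run$history$freq[n] - 2.14) / 2.14, 0.005)
  expect_gt(run$history$omega[n], 0.95)
  # one-step predictions essentially exact after settling
  resid <- tr$angle[4000:n] - run$history$pred[4000:n]
  expect_lt(sqrt(mean(resid^2)) / sd(tr$angle), 0.01)
})

test_that("streaming and batch interfaces agree", {
  tr <- sine_trace(4)
  st <- predictor_init(500)
  for (i in seq_len(1500)) st <- predictor_step(st, tr$angle[i])
  run <- predictor_run(predictor_init(500), tr$angle[1:1500])
  expect_equal(st$phase, run$state$phase, tolerance = 1e-12)
  expect_equal(st$coef, run$state$coef, tolerance = 1e-12)
  expect_equal(st$omega, run$state$omega, tolerance = 1e-12)
  expect_error(predictor_step(st, NaN), class = "fl_stream_error")
})

test_that("quality variable collapses when the input stops being predictable", {
  tr <- sine_trace(10)
  n <- length(tr$t)
  # freeze mid-cycle at 5 s
  y <- c(tr$angle[1:2500], rep(tr$angle[2500], n - 2500))
  run <- predictor_run(predictor_init(500), y)
  om <- run$history$omega
  expect_gt(om[2500], 0.9)
  trip <- which(om[2501:n] < 0.05)[1] / 500
  expect_lt(trip, 2)

  # white noise: unpredictable by construction
  set.seed(31)
  run2 <- predictor_run(predictor_init(500), rnorm(n))
  expect_lt(mean(run2$history$omega[(n - 1000):n]), 0.05)
})

test_that("zero lag is a pass-through to the display clock", {
  tr <- sine_trace(6)
  d <- render_lagged_feedback(tr$t, tr$angle, 0)
  truth <- 20 - 20 * cos(2 * pi * 2.14 * d$t)
  # bounded by the linear-interpolation error of a 2.14 Hz wave at 500 Hz
  expect_lt(max(abs(d$angle - truth)), 40 * (2 * pi * 2.14 / 500)^2 / 8 + 1e-9)
})

test_that("positive lags replay the buffered past", {
  tr <- sine_trace(6)
  d <- render_lagged_feedback(tr$t, tr$angle, 50)
  truth <- 20 - 20 * cos(2 * pi * 2.14 * (d$t - 0.05))
  expect_lt(max(abs(d$angle - truth)), 0.005)
  expect_error(render_lagged_feedback(tr$t, tr$angle, 500),
               class = "fl_parameter_error")
})

test_that("negative-lag reconstruction of periodic input is exact", {
  tr <- sine_trace(10)
  d <- render_lagged_feedback(tr$t, tr$angle, -33)
  truth <- 20 - 20 * cos(2 * pi * 2.14 * (d$t + 0.033))
  keep <- d$t > 5                       # after adaptation settles
  expect_lt(max(abs(d$angle[keep] - truth[keep])) / 40, 0.01)
  # burn-in contract
  expect_error(render_lagged_feedback(tr$t, tr$angle, -33, render_from = 0.5),
               class = "fl_notready_error")
})

test_that("cross-correlation validation recovers constructed shifts", {
  tr <- sine_trace(8)
  # identity
  v0 <- validate_lag(tr, list(t = tr$t, angle = tr$angle))
  expect_equal(v0$peak, 1, tolerance = 1e-9)
  expect_lt(abs(v0$lag_ms), 0.5)
  # shift by exactly 25 samples at 500 Hz = 50 ms
  sh <- 25
  v1 <- validate_lag(list(t = tr$t[1:(4000 - sh)],
                          angle = tr$angle[1:(4000 - sh)]),
                     list(t = tr$t[1:(4000 - sh)],
                          angle = tr$angle[(1 + sh):4000]))
  expect_equal(v1$peak, 1, tolerance = 1e-9)
  expect_equal(v1$lag_ms, -50, tolerance = 0.5)
  expect_error(validate_lag(tr, list(t = tr$t, angle = rep(1, length(tr$t)))),
               class = "fl_degenerate_error")
})

test_that("peak search agrees with a brute-force integer-lag scan", {
  set.seed(5)
  for (rep in 1:3) {
    cyc <- generate_cycles(8, 2.14, cv = 0.04, fs = 500,
                           seed = 100 + rep)
    ang <- 20 - 20 * cos(cyc$phase) + rnorm(length(cyc$t), 0, 0.5)
    sh <- sample(-60:60, 1)
    n <- length(ang)
    idx <- (1 + max(0, sh)):(n + min(0, sh))
    x <- ang[idx]; y <- ang[idx - sh]
    t1 <- (seq_along(x) - 1) / 500
    v <- validate_lag(list(t = t1, angle = x), list(t = t1, angle = y))
    bf <- xcorr_brute(x, y, 125)
    expect_lt(abs(v$lag_ms / 2 - bf$shift), 1)   # within 1 sample
    expect_equal(v$peak, bf$peak, tolerance = 1e-3)
  }
})

test_that("jittered movement at -50 ms is rendered at the right lead", {
  s <- predictor_validation_sim(n_trials = 8, lag_ms = -50, seed = 21)
  expect_lt(abs(s$mean_lag_ms - (-50)), 3)
  expect_gt(s$mean_peak, 0.96)
})

test_that("more cycle jitter never helps the prediction", {
  peaks <- vapply(c(0.01, 0.05, 0.1), function(cv) {
    predictor_validation_sim(n_trials = 6, lag_ms = -33, jitter_cv = cv,
                             seed = 77)$mean_peak
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-4))
})

test_that("quality gating counts and flags correctly", {
  rec <- data.frame(lag_ms = c(-33, -33, -33, 50),
                    omega_min = c(0.04, 0.06, 0.5, NA))
  g <- gate_by_quality(rec, threshold = 0.05)
  expect_equal(g$records$excluded, c(1L, 0L, 0L, 0L))
  expect_equal(g$exclusion_fraction, 1 / 3)
  g2 <- gate_by_quality(data.frame(lag_ms = rep(-50, 4), omega_min = rep(1, 4)))
  expect_equal(g2$exclusion_fraction, 0)
})

test_that("rendering is causal: future samples cannot influence the display", {
  cyc <- generate_cycles(10, 2.14, cv = 0.03, fs = 500, seed = 9)
  ang <- 20 - 20 * cos(cyc$phase)
  d_full <- render_lagged_feedback(cyc$t, ang, -33)
  # corrupt the tail; the display before the corruption must be unchanged
  ang2 <- ang
  ang2[4000:length(ang2)] <- 0
  d_cut <- render_lagged_feedback(cyc$t, ang2, -33)
  t_corrupt <- (4000 - 1) / 500          # time of the first corrupted sample
  before <- d_full$t < t_corrupt - 1e-9
  expect_identical(d_full$angle[before], d_cut$angle[before])
  # same property on the delayed path (linear interp reaches one sample ahead)
  p_full <- render_lagged_feedback(cyc$t, ang, 50)
  p_cut <- render_lagged_feedback(cyc$t, ang2, 50)
  before_p <- p_full$t < t_corrupt + 0.05 - 1 / 500 - 1e-9
  expect_identical(p_full$angle[before_p], p_cut$angle[before_p])
})
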