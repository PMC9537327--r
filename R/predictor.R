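#' Initialize the online cyclic-movement predictor
#'
#' The predictor models the quasi-periodic flexion angle as a truncated
#' Fourier series `a0 + sum_k a_k cos(k*phase) + b_k sin(k*phase)` whose
#' phase and frequency are tracked by a second-order phase-locked loop
#' (proportional + integral correction driven by the normalized product of
#' the one-step prediction error and the waveform's phase sensitivity), and
#' whose harmonic coefficients adapt by normalized least-mean-squares.
#' A prediction-quality state variable `omega` in [0, 1] is maintained as
#' `max(0, 1 - err)` where `err` is the exponentially smoothed (1 s time
#' constant) one-step squared prediction error normalized by the running
#' signal variance; trials whose `omega` falls below 0.05 are unreliable and
#' are excluded downstream.
#'
#' The first `init_secs` seconds (>= 2 movement cycles) are buffered; the
#' base frequency is then estimated from the zero-padded spectrum of the
#' buffer and the harmonic coefficients by least squares, after which the
#' tracker runs causally sample by sample.
#'
#' @param fs sampling rate, Hz.
#' @param K number of harmonics (default 4).
#' @param init_secs burn-in buffer length in seconds.
#' @param eta_coef NLMS step for the Fourier coefficients.
#' @param eta_phase proportional gain of the phase loop (rad per normalized
#'   error unit per sample).
#' @param eta_freq integral gain of the frequency loop.
#' @param tau_err,tau_var time constants (s) of the error and variance
#'   smoothers behind `omega`.
#' @return A `fl_predictor` state object.
#' @export
predictor_init <- function(fs = 500, K = 4, init_secs = 2,
                           eta_coef = 0.01, eta_phase = 0.06,
                           eta_freq = 0.0012, tau_err = 1, tau_var = 2) {
  structure(list(
    fs = fs, dt = 1 / fs, K = K,
    init_n = round(init_secs * fs),
    eta_coef = eta_coef, eta_phase = eta_phase, eta_freq = eta_freq,
    lam_err = exp(-1 / (tau_err * fs)), lam_var = exp(-1 / (tau_var * fs)),
    initialized = FALSE, buffer = numeric(0),
    phase = 0, freq = NA_real_, coef = numeric(2 * K + 1),
    ew_s2 = 1, m_bar = 0, v_bar = 1, err_bar = 0, omega = 0,
    n_seen = 0L
  ), class = "fl_predictor")
}

# Fit frequency + harmonics to the burn-in buffer: spectral peak for f0
# (zero-padded FFT, parabolic refinement), then least squares on the
# harmonic basis.
predictor_bootstrap <- function(state) {
  y <- state$buffer
  n <- length(y)
  fs <- state$fs
  yc <- y - mean(y)
  nfft <- 2^ceiling(log2(n * 8))
  sp <- abs(stats::fft(c(yc * (0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))),
                         numeric(nfft - n))))^2
  f_grid <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  band <- f_grid > 0.5 & f_grid < 8
  i <- which(band)[which.max(sp[seq_len(nfft %/% 2)][band])]
  f0 <- f_grid[i]
  if (i > 1 && i < nfft %/% 2) {      # parabolic peak refinement
    lp <- log(sp[c(i - 1, i, i + 1)] + 1e-300)
    dd <- lp[1] - 2 * lp[2] + lp[3]
    if (dd < 0) f0 <- f0 + 0.5 * (lp[1] - lp[3]) / dd * fs / nfft
  }
  t <- (seq_len(n) - 1) * state$dt
  ph <- 2 * pi * f0 * t
  X <- cbind(1, sapply(seq_len(state$K), function(k) cos(k * ph)),
             sapply(seq_len(state$K), function(k) sin(k * ph)))
  coef <- qr.solve(X, y)
  state$freq <- f0
  state$coef <- coef
  state$phase <- 2 * pi * f0 * n * state$dt
  state$m_bar <- mean(y)
  state$v_bar <- max(stats::var(y), 1e-12)
  resid <- y - X %*% coef
  state$err_bar <- min(1, mean(resid^2) / (state$v_bar / 2))
  state$omega <- max(0, 1 - state$err_bar)
  amp2 <- sum(coef[-1]^2) / 2
  state$ew_s2 <- max(amp2, 1e-8)
  state$initialized <- TRUE
  state
}

# One causal update; `state` must be initialized. Returns list(state, pred).
predictor_update <- function(state, y) {
  K <- state$K
  state$phase <- state$phase + 2 * pi * state$freq * state$dt
  kk <- seq_len(K)
  ck <- cos(kk * state$phase)
  sk <- sin(kk * state$phase)
  a <- state$coef[1 + kk]
  b <- state$coef[1 + K + kk]
  pred <- state$coef[1] + sum(a * ck) + sum(b * sk)
  e <- y - pred
  dpred <- sum(kk * (-a * sk + b * ck))
  state$ew_s2 <- state$lam_err * state$ew_s2 +
    (1 - state$lam_err) * dpred^2
  g <- e * dpred / (state$ew_s2 + 1e-9)
  g <- max(-0.5, min(0.5, g))          # robustify against glitches
  state$phase <- state$phase + state$eta_phase * g
  state$freq <- max(0.1, state$freq + state$eta_freq * g)  # Hz per sample
  basis <- c(1, ck, sk)
  state$coef <- state$coef + state$eta_coef * e * basis / (K + 1)
  # quality bookkeeping
  state$m_bar <- state$lam_var * state$m_bar + (1 - state$lam_var) * y
  dev2 <- (y - state$m_bar)^2
  state$v_bar <- state$lam_var * state$v_bar + (1 - state$lam_var) * dev2
  # normalize by half the running variance: an uninformative prediction at
  # the signal mean scores nerr ~= 2, a locked tracker << 1
  nerr <- e^2 / max(state$v_bar / 2, 1e-12)
  state$err_bar <- state$lam_err * state$err_bar + (1 - state$lam_err) * nerr
  state$omega <- max(0, min(1, 1 - state$err_bar))
  list(state = state, pred = pred)
}

#' Feed one sample to the predictor
#'
#' Streaming entry point: buffers during burn-in, then performs one causal
#' phase/frequency/coefficient update. No future samples are ever used.
#'
#' @param state a `fl_predictor` state.
#' @param sample the new flexion-angle sample.
#' @return The updated state. Its `pred` element (when initialized) holds the
#'   one-step prediction that was compared against `sample`.
#' @export
predictor_step <- function(state, sample) {
  fl_assert(is.finite(sample), "fl_stream_error",
            "non-finite sample fed to predictor")
  state$n_seen <- state$n_seen + 1L
  if (!state$initialized) {
    state$buffer <- c(state$buffer, sample)
    if (length(state$buffer) >= state$init_n) state <- predictor_bootstrap(state)
    state$pred <- NA_real_
    return(state)
  }
  up <- predictor_update(state, sample)
  st <- up$state
  st$pred <- up$pred
  st
}

#' Run the predictor over a whole trace
#'
#' Batch convenience wrapper around the streaming update: identical output to
#' calling [predictor_step()] sample by sample, but with the loop kept
#' internal. Returns the per-sample state history needed for rendering.
#'
#' @param state a `fl_predictor` state (fresh from [predictor_init()] or
#'   carried over from a previous segment).
#' @param samples numeric vector of flexion-angle samples at `state$fs`.
#' @return List with final `state` and `history`: a data frame of per-sample
#'   `phase`, `freq`, `omega`, `pred` (NA during burn-in), plus a matrix
#'   `coef_hist` of Fourier coefficients.
#' @export
predictor_run <- function(state, samples) {
  fl_assert(all(is.finite(samples)), "fl_stream_error",
            "non-finite sample fed to predictor")
  n <- length(samples)
  phase <- freq <- omega <- pred <- rep(NA_real_, n)
  coef_hist <- matrix(NA_real_, n, 2 * state$K + 1)
  for (i in seq_len(n)) {
    state$n_seen <- state$n_seen + 1L
    if (!state$initialized) {
      state$buffer <- c(state$buffer, samples[i])
      if (length(state$buffer) >= state$init_n)
        state <- predictor_bootstrap(state)
    } else {
      up <- predictor_update(state, samples[i])
      state <- up$state
      pred[i] <- up$pred
    }
    if (state$initialized) {
      phase[i] <- state$phase; freq[i] <- state$freq
      omega[i] <- state$omega; coef_hist[i, ] <- state$coef
    }
  }
  list(state = state,
       history = data.frame(phase = phase, freq = freq, omega = omega,
                            pred = pred),
       coef_hist = coef_hist)
}

harmonic_eval <- function(coef, K, phase) {
  kk <- seq_len(K)
  coef[1] + sapply(phase, function(p) {
    sum(coef[1 + kk] * cos(kk * p)) + sum(coef[1 + K + kk] * sin(kk * p))
  })
}

#' Render temporally shifted visual feedback
#'
#' Produces the displayed-angle track at the display rate for a signed lag.
#' Positive lags replay buffered past samples delayed by `lag_ms`
#' (interpolated to the display clock); negative lags evaluate the
#' predictor's harmonic reconstruction at `phase + 2*pi*freq*|lag|/1000`,
#' i.e. the movement is extrapolated ahead of the hand using only past
#' samples; zero lag passes the input through, resampled to the display
#' clock. Causality holds on every path.
#'
#' @param t time vector (s) of the captured trace, uniformly sampled at `fs`.
#' @param angle flexion-angle samples.
#' @param lag_ms signed lag in ms (positive = display lags the hand).
#' @param fs capture rate, Hz.
#' @param display_rate display clock, Hz.
#' @param lag_bounds permitted `c(min, max)` lag in ms.
#' @param predictor optional pre-configured [predictor_init()] state
#'   (negative lags only).
#' @param render_from earliest display time (s, relative to `t[1]`); for
#'   negative lags defaults to the predictor burn-in plus 1 s of settling.
#'   Requesting earlier output than the burn-in allows is a not-ready error.
#' @return A list of class `fl_display`: `t`, `angle`, `lag_ms`, and (for
#'   negative lags) per-tick `omega` and `freq`.
#' @export
render_lagged_feedback <- function(t, angle, lag_ms, fs = 500,
                                   display_rate = 60,
                                   lag_bounds = c(-50, 83),
                                   predictor = NULL,
                                   render_from = NULL) {
  fl_assert(lag_ms >= lag_bounds[1] && lag_ms <= lag_bounds[2],
            "fl_parameter_error",
            "lag %g ms outside configured bounds [%g, %g]",
            lag_ms, lag_bounds[1], lag_bounds[2])
  lag_s <- lag_ms / 1000
  dt_d <- 1 / display_rate
  t0 <- t[1]

  if (lag_ms >= 0) {
    start <- if (is.null(render_from)) lag_s else max(render_from, lag_s)
    td <- seq(t0 + start, t[length(t)], by = dt_d)
    # local (linear) interpolation keeps the path strictly causal
    ang <- stats::approx(t, angle, xout = td - lag_s, rule = 2)$y
    return(structure(list(t = td, angle = ang, lag_ms = lag_ms),
                     class = "fl_display"))
  }

  if (is.null(predictor)) predictor <- predictor_init(fs = fs)
  burn <- predictor$init_n / fs + 1
  if (is.null(render_from)) render_from <- burn
  fl_assert(render_from >= burn, "fl_notready_error",
            "negative-lag rendering requested at %.2f s but predictor burn-in needs %.2f s",
            render_from, burn)
  run <- predictor_run(predictor, angle)
  h <- run$history
  td <- seq(t0 + render_from, t[length(t)], by = dt_d)
  idx <- pmin(length(t), pmax(1, floor((td - t0) * fs) + 1))
  adv <- 2 * pi * h$freq[idx] * abs(lag_s)
  extra <- 2 * pi * h$freq[idx] * (td - t[idx])   # sub-sample clock alignment
  K <- predictor$K
  ang <- vapply(seq_along(td), function(j) {
    harmonic_eval(run$coef_hist[idx[j], ], K,
                  h$phase[idx[j]] + adv[j] + extra[j])
  }, numeric(1))
  structure(list(t = td, angle = ang, lag_ms = lag_ms,
                 omega = h$omega[idx], freq = h$freq[idx]),
            class = "fl_display")
}

#' Validate rendered feedback by cross-correlation
#'
#' Interpolates the displayed track onto the capture grid over the common
#' time support, mean-removes both signals, scans the normalized
#' cross-correlation over integer lags within a window (default +/-250 ms at
#' the capture resolution) and refines the peak by parabolic interpolation
#' around the discrete argmax. Positive recovered lag means the display lags
#' the hand.
#'
#' @param actual list/data frame with `t` and `angle` of the captured trace.
#' @param displayed an `fl_display` track (or list with `t`, `angle`).
#' @param fs capture rate, Hz.
#' @param max_lag_ms half-width of the searched lag window, ms.
#' @param window optional `c(start, end)` time window (s) to restrict the
#'   comparison (e.g. the test period).
#' @return List of class `fl_lag_validation`: `peak` (normalized, <= 1),
#'   `lag_ms` (signed, sub-sample refined), `n` (samples compared).
#' @export
validate_lag <- function(actual, displayed, fs = 500, max_lag_ms = 250,
                         window = NULL) {
  t_lo <- max(min(actual$t), min(displayed$t))
  t_hi <- min(max(actual$t), max(displayed$t))
  if (!is.null(window)) {
    t_lo <- max(t_lo, window[1]); t_hi <- min(t_hi, window[2])
  }
  fl_assert(t_hi - t_lo > 0.5, "fl_data_error",
            "overlapping support too short (%.2f s)", t_hi - t_lo)
  tg <- seq(t_lo, t_hi, by = 1 / fs)
  x <- resample_series(actual$t, actual$angle, tg)
  y <- resample_series(displayed$t, displayed$angle, tg)
  fl_assert(stats::sd(x) > 1e-12 && stats::sd(y) > 1e-12,
            "fl_degenerate_error",
            "constant input: cross-correlation undefined")
  x <- x - mean(x); y <- y - mean(y)
  m <- round(max_lag_ms / 1000 * fs)
  n <- length(x)
  fl_assert(n > 2 * m + 10, "fl_data_error",
            "window too short for +/-%g ms lag scan", max_lag_ms)
  shifts <- -m:m
  r <- vapply(shifts, function(s) {
    if (s >= 0) stats::cor(x[1:(n - s)], y[(1 + s):n])
    else stats::cor(x[(1 - s):n], y[1:(n + s)])
  }, numeric(1))
  i <- which.max(r)
  peak <- r[i]
  lag <- shifts[i] / fs
  if (i > 1 && i < length(r)) {        # sub-sample parabolic refinement
    dd <- r[i - 1] - 2 * r[i] + r[i + 1]
    if (dd < 0) {
      delta <- 0.5 * (r[i - 1] - r[i + 1]) / dd
      lag <- (shifts[i] + delta) / fs
      peak <- r[i] - 0.25 * (r[i - 1] - r[i + 1]) * delta
    }
  }
  structure(list(peak = peak, lag_ms = lag * 1000, n = n),
            class = "fl_lag_validation")
}

#' Gate trials on prediction quality
#'
#' Flags negative-lag trials whose minimum prediction quality over the test
#' period fell below the threshold (default 0.05) as excluded, and reports
#' the exclusion fraction over negative-lag trials.
#'
#' @param records trial records with `lag_ms` and `omega_min` columns.
#' @param threshold quality threshold.
#' @return List with `records` (exclusion flags updated) and
#'   `exclusion_fraction` (NA if there are no negative-lag trials).
#' @export
gate_by_quality <- function(records, threshold = 0.05) {
  neg <- records$lag_ms < 0
  bad <- neg & !is.na(records$omega_min) & records$omega_min < threshold
  records$excluded <- as.integer(bad)
  frac <- if (any(neg)) mean(bad[neg]) else NA_real_
  list(records = records, exclusion_fraction = frac)
}

#' End-to-end predictor validation simulation
#'
#' Reproduces the validation protocol of the preceding-feedback condition on
#' synthetic movement: each trial simulates paced cyclic flexion (default
#' 2.14 Hz, 3% cycle jitter, participant-specific span drawn from 38-55
#' degrees) through a burn-in plus a 9-s test window, renders the negatively
#' lagged feedback with the online predictor, gates on the minimum quality
#' `omega` over the test window, and measures the peak normalized
#' cross-correlation and its lag against the actual trajectory.
#'
#' @param n_trials number of simulated trials.
#' @param lag_ms negative lag to render, ms.
#' @param f0 movement frequency, Hz.
#' @param jitter_cv cycle-period jitter CV.
#' @param test_s test-window length, s.
#' @param burn_s burn-in before the test window, s.
#' @param fs,display_rate capture and display rates, Hz.
#' @param threshold quality gate.
#' @param seed master seed.
#' @return List with `trials` (per-trial peak, lag_ms, omega_min, excluded),
#'   `mean_peak`, `mean_lag_ms` (over retained trials), `exclusion_fraction`,
#'   `n_retained`.
#' @export
predictor_validation_sim <- function(n_trials = 120, lag_ms = -33,
                                     f0 = 2.14, jitter_cv = 0.03,
                                     test_s = 9, burn_s = 5,
                                     fs = 500, display_rate = 60,
                                     threshold = 0.05, seed = 1L) {
  fl_assert(lag_ms < 0, "fl_parameter_error",
            "validation protocol is for negative lags")
  res <- lapply(seq_len(n_trials), function(tr) {
    s <- substream_seed(seed, "valsim", lag_ms, tr)
    span <- with_seed(substream_seed(s, "span"), stats::runif(1, 38, 55))
    cyc <- generate_cycles(burn_s + test_s, f0, jitter_cv, fs,
                           seed = substream_seed(s, "kin"))
    angle <- span / 2 - span / 2 * cos(cyc$phase)
    disp <- render_lagged_feedback(cyc$t, angle, lag_ms, fs = fs,
                                   display_rate = display_rate,
                                   render_from = burn_s)
    win <- c(burn_s, burn_s + test_s)
    v <- validate_lag(list(t = cyc$t, angle = angle), disp, fs = fs,
                      window = win)
    in_win <- disp$t >= win[1] & disp$t <= win[2]
    data.frame(trial = tr, peak = v$peak, lag_ms = v$lag_ms,
               omega_min = min(disp$omega[in_win]))
  })
  trials <- do.call(rbind, res)
  trials$lag_nominal <- lag_ms
  gated <- gate_by_quality(
    data.frame(lag_ms = trials$lag_nominal, omega_min = trials$omega_min),
    threshold)
  trials$excluded <- gated$records$excluded
  keep <- trials$excluded == 0L
  list(trials = trials,
       mean_peak = mean(trials$peak[keep]),
       mean_lag_ms = mean(trials$lag_ms[keep]),
       exclusion_fraction = gated$exclusion_fraction,
       n_retained = sum(keep))
}
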