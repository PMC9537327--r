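# Zero-phase 4th-order Butterworth band-pass, applied forward-backward
# (offline analysis; doubles the attenuation, cancels phase).
emg_bandpass <- function(x, fs = 500, band = c(20, 240), order = 4) {
  fl_assert(all(is.finite(x)), "fl_data_error", "EMG contains non-finite samples")
  fl_assert(band[2] < fs / 2, "fl_parameter_error",
            "upper band edge (%g Hz) must be below Nyquist (%g Hz)",
            band[2], fs / 2)
  fl_assert(band[1] > 0 && band[1] < band[2], "fl_parameter_error",
            "band edges must satisfy 0 < low < high")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Preprocess surface EMG
#'
#' Band-pass filters (4th-order Butterworth, 20-240 Hz, zero-phase
#' forward-backward) and then full-wave rectifies the raw EMG. The 20-240 Hz
#' band retains the bulk of surface-EMG power while excluding motion artifact
#' below 20 Hz.
#'
#' @param x raw EMG samples.
#' @param fs sampling rate, Hz (default 500).
#' @param band band edges in Hz.
#' @param order filter order.
#' @return Rectified, band-passed trace of the same length.
#' @export
emg_preprocess <- function(x, fs = 500, band = c(20, 240), order = 4) {
  abs(emg_bandpass(x, fs, band, order))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed segments (default 2 s) with
#' 50% overlap.
#'
#' @param x signal samples.
#' @param fs sampling rate, Hz.
#' @param window_s segment length in seconds.
#' @return List with `freq` (Hz) and `psd` (one-sided, arbitrary scale).
#' @export
welch_psd <- function(x, fs = 500, window_s = 2) {
  nw <- round(window_s * fs)
  fl_assert(length(x) >= nw, "fl_parameter_error",
            "signal shorter (%d samples) than one analysis window (%d)",
            length(x), nw)
  step <- nw %/% 2
  starts <- seq(1, length(x) - nw + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))
  acc <- numeric(nw %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nw %/% 2 + 1)]
  }
  list(freq = (seq_len(nw %/% 2 + 1) - 1) * fs / nw,
       psd = acc / length(starts))
}

#' EMG median frequency
#'
#' Frequency splitting the band-limited spectral power into equal halves.
#' The raw signal is band-passed (zero-phase Butterworth, not rectified), its
#' PSD estimated by Welch's method (2 s Hann windows, 50% overlap), and the
#' cumulative in-band power inverted by linear interpolation. To stay
#' well-defined when the cumulative power plateaus at one half (e.g. two
#' equal-power spectral lines), the returned value is the midpoint of the
#' 49.9% and 50.1% power quantiles, which collapses to the usual median for
#' continuous spectra.
#'
#' @param x raw EMG samples.
#' @param fs sampling rate, Hz.
#' @param band analysis band, Hz.
#' @param window_s Welch segment length in seconds; the signal must contain at
#'   least one full window (>= 2 s at the default).
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(x, fs = 500, band = c(20, 240), window_s = 2) {
  fl_assert(length(x) >= window_s * fs, "fl_parameter_error",
            "median_frequency needs >= %g s of signal", window_s)
  xf <- emg_bandpass(x, fs, band)
  sp <- welch_psd(xf, fs, window_s)
  keep <- sp$freq >= band[1] & sp$freq <= band[2]
  f <- sp$freq[keep]
  p <- sp$psd[keep]
  cum <- cumsum(p)
  cum <- cum / cum[length(cum)]
  qf <- function(q) stats::approx(cum, f, xout = q, ties = "ordered",
                                  rule = 2)$y
  mean(c(qf(0.499), qf(0.501)))
}

#' Kinematic and EMG movement indices over a window
#'
#' Computes, from a flexion-angle trace, the per-cycle movement amplitude
#' (difference between the maximal and minimal peak within each cycle),
#' the mean absolute angular velocity, and the movement cycle interval
#' (spacing between successive flexion-direction crossings of the center of
#' the target lines, located by linear interpolation between samples).
#' If preprocessed EMG is supplied its mean (average rectified value) over
#' the window is included.
#'
#' @param t time vector, s.
#' @param angle flexion angle, degrees.
#' @param center center of the two target lines, degrees (crossings of this
#'   line while flexing delimit cycles). Defaults to the trace midrange.
#' @param emg optional named list of preprocessed (rectified) EMG vectors on
#'   the same grid.
#' @return List with `amplitude_deg`, `velocity_deg_s`, `interval_s`,
#'   `n_cycles`, and `arv_<channel>` entries for each EMG channel.
#' @export
cycle_metrics <- function(t, angle, center = NULL, emg = NULL) {
  fl_assert(length(t) == length(angle) && length(t) > 2, "fl_data_error",
            "t and angle must be equal-length vectors")
  if (is.null(center)) center <- (max(angle) + min(angle)) / 2
  d <- angle - center
  # flexion-direction (rising) crossings; interpolate the crossing time
  idx <- which(d[-length(d)] < 0 & d[-1] >= 0)
  fl_assert(length(idx) >= 3, "fl_degenerate_error",
            "fewer than 3 flexion crossings of the center line (need >= 2 cycles)")
  frac <- -d[idx] / (d[idx + 1] - d[idx])
  t_cross <- t[idx] + frac * (t[idx + 1] - t[idx])
  intervals <- diff(t_cross)

  amps <- vapply(seq_len(length(idx) - 1), function(k) {
    seg <- angle[idx[k]:idx[k + 1]]
    max(seg) - min(seg)
  }, numeric(1))

  vel <- abs(diff(angle) / diff(t))
  out <- list(amplitude_deg = mean(amps),
              velocity_deg_s = mean(vel),
              interval_s = mean(intervals),
              n_cycles = length(intervals))
  if (!is.null(emg)) {
    for (nm in names(emg)) out[[paste0("arv_", nm)]] <- mean(emg[[nm]])
  }
  out
}

#' Normalized condition-difference index
#'
#' The change in a movement index caused by displaying the comparison
#' (lagged) rather than the standard (synchronous) feedback, normalized by
#' the participant's baseline value of that index:
#' `delta = (I_comparison - I_standard) / I_baseline`. Vectorized.
#'
#' @param i_comparison,i_standard index values under comparison and standard
#'   stimuli.
#' @param i_baseline baseline normalizer (> 0), e.g. the index averaged over
#'   non-delayed preparation periods.
#' @return Numeric vector of normalized changes.
#' @export
delta_index <- function(i_comparison, i_standard, i_baseline) {
  fl_assert(all(i_baseline > 0), "fl_domain_error",
            "i_baseline must be positive")
  (i_comparison - i_standard) / i_baseline
}
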