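#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish config/data/schedule problems
# programmatically (tryCatch on the class, not on message text).
fl_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "fl_error")))
}

fl_assert <- function(cond, class, msg, ...) {
  if (!isTRUE(cond)) fl_stop(class, msg, ...)
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one master seed; independent
#' sub-streams (per participant, block, purpose) are derived by hashing the
#' master seed together with a string key. The hash is a small deterministic
#' polynomial over the key bytes, reduced modulo 2^31 - 1 so the result is
#' always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param ... strings or numbers identifying the sub-stream
#'   (e.g. participant id, block index, "emg").
#' @return A single integer seed.
#' @export
substream_seed <- function(master, ...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = "|"),
                      character(1)), collapse = "/")
  bytes <- utf8ToInt(key)
  h <- as.numeric(master) %% 2147483647
  for (b in bytes) h <- (h * 69069 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Cubic-spline resampling of a uniformly sampled series onto new times.
resample_series <- function(t, x, t_new) {
  stats::spline(t, x, xout = t_new, method = "fmm")$y
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 1
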