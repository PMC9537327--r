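# Canonical column sets for the on-disk CSV schemas. Readers are name-keyed
# (column order is free) but strict: a missing or unknown column is a schema
# error naming the offender.

TRIALS_SCHEMA <- c("participant_id", "experiment", "session", "block",
                   "trial", "sound", "lag_ms", "comparison_phase",
                   "choice_comparison", "omega_min", "excluded")

METRICS_SCHEMA <- c("participant_id", "block", "trial", "phase", "lag_ms",
                    "sound", "amplitude_deg", "velocity_deg_s", "interval_s",
                    "arv_flexor", "arv_extensor", "mf_flexor_hz",
                    "mf_extensor_hz")

check_schema <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  fl_assert(length(missing) == 0, "fl_schema_error",
            "%s: missing column(s): %s", what, paste(missing, collapse = ", "))
  unknown <- setdiff(names(df), schema)
  fl_assert(length(unknown) == 0, "fl_schema_error",
            "%s: unknown column(s): %s", what, paste(unknown, collapse = ", "))
  df[, schema, drop = FALSE]
}

#' Write / read trial tables
#'
#' Trial records round-trip through a fixed name-keyed CSV schema
#' (`participant_id, experiment, session, block, trial, sound, lag_ms,
#' comparison_phase, choice_comparison, omega_min, excluded`); numeric fields
#' are written at full precision (15 significant digits). Extra in-memory
#' columns (e.g. `p_true`) are dropped on write.
#'
#' @param records trial records data frame.
#' @param path CSV path.
#' @return `write_trials` returns the path invisibly; `read_trials` the
#'   records.
#' @export
write_trials <- function(records, path) {
  df <- records
  for (col in TRIALS_SCHEMA) if (is.null(df[[col]])) {
    df[[col]] <- if (col == "excluded") 0L else NA
  }
  df <- df[, TRIALS_SCHEMA, drop = FALSE]
  write_csv_full(df, path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read_csv_checked(path)
  df <- check_schema(df, TRIALS_SCHEMA, basename(path))
  num <- c("block", "trial", "sound", "lag_ms", "comparison_phase",
           "choice_comparison", "omega_min", "excluded")
  bad <- vapply(num, function(cl) any(is.infinite(df[[cl]])), logical(1))
  fl_assert(!any(bad), "fl_data_error", "non-finite values in column(s): %s",
            paste(num[bad], collapse = ", "))
  df
}

#' Write / read sampled traces
#'
#' Kinematic traces use columns `t_s, angle_deg`; EMG traces use
#' `t_s, emg_flexor, emg_extensor`. A JSON sidecar (same path with
#' `.json` appended) records the sampling rate and any ground-truth metadata.
#'
#' @param t time vector, s.
#' @param path CSV path.
#' @param angle_deg flexion angle (kinematic trace).
#' @param fs sampling rate recorded in the sidecar.
#' @param meta extra named metadata for the sidecar.
#' @return Path, invisibly.
#' @export
write_kinematic_trace <- function(t, angle_deg, path, fs = 500, meta = list()) {
  write_csv_full(data.frame(t_s = t, angle_deg = angle_deg), path)
  jsonlite::write_json(c(list(sampling_rate_hz = fs, kind = "kinematic"),
                         meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinematic_trace
#' @param emg_flexor,emg_extensor EMG channels.
#' @export
write_emg_trace <- function(t, emg_flexor, emg_extensor, path, fs = 500,
                            meta = list()) {
  write_csv_full(data.frame(t_s = t, emg_flexor = emg_flexor,
                            emg_extensor = emg_extensor), path)
  jsonlite::write_json(c(list(sampling_rate_hz = fs, kind = "emg"), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinematic_trace
#' @export
read_trace <- function(path) {
  df <- read_csv_checked(path)
  fl_assert("t_s" %in% names(df), "fl_schema_error",
            "%s: missing column(s): t_s", basename(path))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  list(data = df, meta = meta)
}

write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (cl in names(df)[num]) {
    v <- df[[cl]]
    out[[cl]] <- ifelse(is.na(v), "",
                        ifelse(v == round(v) & abs(v) < 1e15,
                               format(v, scientific = FALSE, trim = TRUE),
                               format(v, digits = 15, trim = TRUE)))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_checked <- function(path) {
  fl_assert(file.exists(path), "fl_dependency_error",
            "missing input file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
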