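#' Load and validate a pipeline configuration
#'
#' Accepts a JSON file path or a list. Required fields: `experiment` (1|2).
#' Optional: `n_participants`, `blocks_per_participant`, `delay_blocks`,
#' `seed`, `traces` (simulate kinematics/EMG and movement metrics),
#' `model` (generating model 1-3), `jitter_cv`, `lag_conditions` (override;
#' validated against the rendering bounds of -50..+83 ms),
#' `n_validation_trials` (run the preceding-feedback validation simulation).
#' Violations raise a config error naming the field.
#'
#' @param config path to a JSON config or a named list.
#' @return Validated list of settings (class `fl_pipeline_config`).
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    fl_assert(file.exists(config), "fl_config_error",
              "config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  fl_assert(is.list(config), "fl_config_error", "config must be a list")
  fl_assert(!is.null(config$experiment), "fl_config_error",
            "config$experiment: required (1 or 2)")
  fl_assert(config$experiment %in% c(1, 2), "fl_config_error",
            "config$experiment: must be 1 or 2")
  defaults <- list(n_participants = 14, blocks_per_participant = 15,
                   delay_blocks = if (config$experiment == 1) 12 else 10,
                   seed = 1L, traces = FALSE, model = 1, jitter_cv = 0.03,
                   lag_conditions = NULL, n_validation_trials = 0)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  fl_assert(is_count(config$n_participants), "fl_config_error",
            "config$n_participants: must be a positive integer")
  fl_assert(is_count(config$blocks_per_participant), "fl_config_error",
            "config$blocks_per_participant: must be a positive integer")
  fl_assert(config$model %in% 1:3, "fl_config_error",
            "config$model: must be 1, 2 or 3")
  if (!is.null(config$lag_conditions)) {
    ok <- all(config$lag_conditions >= -50 & config$lag_conditions <= 83)
    fl_assert(ok, "fl_config_error",
              "config$lag_conditions: lags must lie within [-50, 83] ms")
  }
  unknown <- setdiff(names(config), c(names(defaults), "experiment"))
  fl_assert(length(unknown) == 0, "fl_config_error",
            "config: unknown field(s): %s", paste(unknown, collapse = ", "))
  structure(config, class = "fl_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> (optional) movement/EMG metrics -> (optional)
#' preceding-feedback validation -> psychometric fits -> inferential
#' statistics -> report, writing every stage's outputs plus a provenance
#' manifest into `outdir`. Identical config + seed reproduce identical
#' tables.
#'
#' Outputs: `trials.csv`, `delay_trials.csv`, `fits.json`, `slopes.csv`,
#' `stats_report.json`, `metrics.csv` (traces only), `validation.json`
#' (validation trials only), `report.txt`, `manifest.json`.
#'
#' @param config path to JSON config or list (see [load_config()]).
#' @param outdir output directory (created if absent).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  cfgin <- load_config(config)
  if (!is.null(seed)) cfgin$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  cfg <- exp_config(cfgin$experiment,
                    n_participants = cfgin$n_participants,
                    blocks_per_participant = cfgin$blocks_per_participant,
                    delay_blocks = cfgin$delay_blocks,
                    jitter_cv = cfgin$jitter_cv,
                    rng_seed = cfgin$seed)
  if (!is.null(cfgin$lag_conditions)) {
    cfg$lag_conditions <- sort(cfgin$lag_conditions)
  }
  cohort <- make_cohort(cfg, seed = cfgin$seed, model = cfgin$model)
  ds <- build_dataset(cfg, cohort, seed = cfgin$seed,
                      traces = isTRUE(cfgin$traces))

  write_trials(ds$trials, file.path(outdir, "trials.csv"))
  write_trials(ds$delay_trials, file.path(outdir, "delay_trials.csv"))

  metrics <- NULL
  if (isTRUE(cfgin$traces)) {
    metrics <- compute_metrics(ds)
    write_csv_full(metrics$table, file.path(outdir, "metrics.csv"))
  }

  validation <- NULL
  if (cfgin$n_validation_trials > 0) {
    neg <- cfg$lag_conditions[cfg$lag_conditions < 0]
    validation <- lapply(neg, function(l) {
      predictor_validation_sim(n_trials = cfgin$n_validation_trials,
                               lag_ms = l, jitter_cv = cfg$jitter_cv,
                               seed = substream_seed(cfgin$seed, "val", l))
    })
    names(validation) <- paste0("lag_", neg)
    jsonlite::write_json(
      lapply(validation, function(v) {
        list(per_trial = v$trials, mean_peak = v$mean_peak,
             mean_lag_ms = v$mean_lag_ms,
             exclusion_fraction = v$exclusion_fraction)
      }),
      file.path(outdir, "validation.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }

  fits <- fit_session_models(ds)
  jsonlite::write_json(fits$json, file.path(outdir, "fits.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fits$slopes)) {
    write_csv_full(fits$slopes, file.path(outdir, "slopes.csv"))
  }

  stats_res <- session_statistics(ds)
  jsonlite::write_json(stats_res, file.path(outdir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA)

  rpt <- report(ds, fits, stats_res, validation)
  writeLines(rpt, file.path(outdir, "report.txt"))

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = cfgin$seed,
    config = unclass(cfgin),
    package_version = as.character(utils::packageVersion("fatiguelag")),
    generated_at = format(Sys.time(), tz = "UTC"),
    digests = as.list(tools::md5sum(files))
  )
  names(manifest$digests) <- basename(files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(config = cfg, dataset = ds, metrics = metrics,
                 validation = validation, fits = fits, stats = stats_res,
                 report = rpt, outdir = outdir))
}

# Fit models 1-3 to the fatigue session (pd from the delay session), model 1
# to the delay session, and correlate participant slopes across tasks.
fit_session_models <- function(ds) {
  fat <- ds$trials[ds$trials$excluded == 0L, ]
  key <- paste(fat$participant_id, fat$lag_ms)
  pdt <- ds$pd_table
  fat$pd <- pdt$pd[match(key, paste(pdt$participant_id, pdt$lag_ms))]
  d_fat <- data.frame(participant_id = fat$participant_id, x = fat$lag_ms,
                      y = fat$choice_comparison, pd = fat$pd)
  del <- ds$delay_trials
  d_del <- data.frame(participant_id = del$participant_id,
                      x = abs(del$lag_ms), y = del$choice_comparison)

  m1 <- fit_probit_glmm(d_fat, model = 1)
  m2 <- fit_probit_glmm(d_fat, model = 2)
  m3 <- fit_probit_glmm(d_fat, model = 3)
  md <- fit_probit_glmm(d_del, model = 1)
  ranking <- model_comparison_aic(m1, m2, m3)
  sc <- slope_correlation(m1, md)

  fit_json <- function(f) list(
    model = f$model, fixed = as.list(f$fixed), se = as.list(f$se),
    re_sd = as.list(f$re_sd), loglik = f$loglik, aic = f$aic, k = f$k,
    converged = f$converged)
  list(m1 = m1, m2 = m2, m3 = m3, delay = md, ranking = ranking,
       slope_correlation = sc,
       slopes = sc$slopes,
       json = list(models = lapply(list(m1, m2, m3), fit_json),
                   delay_task = fit_json(md),
                   ranking = ranking,
                   slope_correlation = sc[c("r", "p", "df")]))
}

# Chance-level t tests per lag (Holm-adjusted), lag x task RM-ANOVA, and
# (experiment 1) lag x sound RM-ANOVA on the fatigue choice proportions.
session_statistics <- function(ds) {
  ct_f <- choice_table(ds$trials, by_sound = FALSE)
  ct_d <- choice_table(ds$delay_trials, by_sound = FALSE)

  lags <- sort(unique(ct_f$lag_ms))
  lags_t <- setdiff(lags, 0)
  tests <- lapply(lags_t, function(l) {
    v <- ct_f$proportion[ct_f$lag_ms == l]
    tt <- t_tests(v, mu0 = 0.5)
    list(name = sprintf("fatigue choice vs chance at %+d ms", l),
         lag_ms = l, statistic = tt$statistic, df = tt$df, p_raw = tt$p,
         effect_size = tt$d, method = tt$method)
  })
  p_adj <- holm_adjust(vapply(tests, function(x) x$p_raw, numeric(1)))
  for (i in seq_along(tests)) tests[[i]]$p_adj <- p_adj[i]

  # lag x task ANOVA on the lags common to both sessions
  common <- intersect(ct_f$lag_ms, ct_d$lag_ms)
  both <- rbind(
    data.frame(subject = ct_f$participant_id, lag = ct_f$lag_ms,
               task = "fatigue", value = ct_f$proportion)[
                 ct_f$lag_ms %in% common, ],
    data.frame(subject = ct_d$participant_id, lag = ct_d$lag_ms,
               task = "delay", value = ct_d$proportion)[
                 ct_d$lag_ms %in% common, ])
  an_task <- rm_anova_2way(both, "subject", "lag", "task", "value")

  an_sound <- NULL
  if (length(unique(ds$trials$sound)) > 1) {
    ct_s <- choice_table(ds$trials, by_sound = TRUE)
    an_sound <- rm_anova_2way(
      data.frame(subject = ct_s$participant_id, lag = ct_s$lag_ms,
                 sound = ct_s$sound, value = ct_s$proportion),
      "subject", "lag", "sound", "value")
  }

  anova_json <- function(an) {
    if (is.null(an)) return(NULL)
    lapply(an[c("A", "B", "AB")], function(e) {
      list(F = e$F, df = e$df, p = e$p, partial_eta_sq = e$pes)
    })
  }
  list(chance_tests = tests,
       anova_lag_task = anova_json(an_task),
       anova_lag_sound = anova_json(an_sound),
       sample_size_d1 = sample_size_t(d = 1.00, alpha = 0.05, power = 0.8))
}

#' Human-readable pipeline summary
#'
#' @param ds an `fl_dataset`.
#' @param fits result of the model-fitting stage.
#' @param stats_res result of the statistics stage.
#' @param validation optional predictor-validation results.
#' @return Character vector of report lines.
#' @export
report <- function(ds, fits, stats_res, validation = NULL) {
  ct <- choice_table(ds$trials, by_sound = FALSE)
  lines <- c(sprintf("Experiment %d synthetic run: %d participants",
                     ds$config$experiment_id, ds$config$n_participants),
             "", "Fatigue-session choice probability by lag (mean +/- se):")
  for (l in sort(unique(ct$lag_ms))) {
    v <- ct$proportion[ct$lag_ms == l]
    lines <- c(lines, sprintf("  %+4d ms: %.3f +/- %.3f", l, mean(v),
                              stats::sd(v) / sqrt(length(v))))
  }
  excl <- ds$trials$excluded
  neg <- ds$trials$lag_ms < 0
  frac <- if (any(neg)) 100 * mean(excl[neg] == 1L) else 0
  lines <- c(lines, "",
             sprintf("Negative-lag trials excluded by quality gate: %.1f%%",
                     frac),
             "", "Model comparison (AIC):")
  rk <- fits$ranking
  for (i in seq_len(nrow(rk))) {
    lines <- c(lines, sprintf("  model %d: AIC %.1f (delta %.1f)%s",
                              rk$model[i], rk$aic[i], rk$delta_aic[i],
                              if (rk$best[i]) "  <- best" else ""))
  }
  sc <- fits$slope_correlation
  lines <- c(lines, "",
             if (is.na(sc$r)) "Fatigue vs delay participant slopes: n/a" else
               sprintf("Fatigue vs delay participant slopes: r = %.2f, p = %.3f",
                       sc$r, sc$p),
             "", "Chance-level tests (Holm-adjusted):")
  for (tst in stats_res$chance_tests) {
    lines <- c(lines, sprintf("  %s: t(%d) = %.2f, p_adj = %.4f, d = %.2f",
                              tst$name, tst$df, tst$statistic, tst$p_adj,
                              tst$effect_size))
  }
  if (!is.null(validation)) {
    lines <- c(lines, "", "Preceding-feedback validation:")
    for (nm in names(validation)) {
      v <- validation[[nm]]
      lines <- c(lines, sprintf(
        "  %s: mean peak r = %.3f, mean lag = %.1f ms, excluded %.1f%%",
        nm, v$mean_peak, v$mean_lag_ms, 100 * v$exclusion_fraction))
    }
  }
  lines
}

#' Movement and EMG metrics for a dataset with traces
#'
#' For every trial of every simulated block: kinematic indices
#' ([cycle_metrics()]) and EMG measures (ARV of the preprocessed signal,
#' median frequency of each channel) in both phases of the test period, and
#' the normalized change `delta = (comparison - standard) / baseline` per
#' index, with the participant baseline taken from preparation periods that
#' displayed synchronous feedback.
#'
#' @param ds an `fl_dataset` built with `traces = TRUE`.
#' @return List with `table` (per trial x phase metrics) and `deltas`
#'   (per trial normalized changes).
#' @export
compute_metrics <- function(ds) {
  fl_assert(!is.null(ds$blocks), "fl_dependency_error",
            "dataset was built without traces")
  rows <- list(); drows <- list()
  for (key in names(ds$blocks)) {
    blk <- ds$blocks[[key]]
    pid <- sub("_[0-9]+$", "", key)
    b <- as.integer(sub("^.*_", "", key))
    part <- ds$cohort$participants[ds$cohort$participants$id == pid, ]
    center <- part$amplitude_deg / 2
    fs <- ds$config$capture_rate
    kin <- blk$kin; emg <- blk$emg
    emg_f <- emg_preprocess(emg$flexor, fs)
    emg_e <- emg_preprocess(emg$extensor, fs)
    slice <- function(w) kin$t >= w[1] & kin$t < w[2]
    for (i in seq_len(nrow(blk$windows))) {
      w <- blk$windows[i, ]
      for (ph in 1:2) {
        win <- if (ph == 1) c(w$phase1_start, w$phase1_end) else
          c(w$phase2_start, w$phase2_end)
        sl <- slice(win)
        cm <- cycle_metrics(kin$t[sl], kin$angle_deg[sl], center = center,
                            emg = list(flexor = emg_f[sl],
                                       extensor = emg_e[sl]))
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = pid, block = b, trial = w$trial, phase = ph,
          lag_ms = w$lag_ms, sound = w$sound,
          amplitude_deg = cm$amplitude_deg,
          velocity_deg_s = cm$velocity_deg_s,
          interval_s = cm$interval_s,
          arv_flexor = cm$arv_flexor, arv_extensor = cm$arv_extensor,
          mf_flexor_hz = median_frequency(emg$flexor[sl], fs),
          mf_extensor_hz = median_frequency(emg$extensor[sl], fs),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)

  # participant baselines from synchronous-feedback preparation periods
  base <- list()
  for (key in names(ds$blocks)) {
    blk <- ds$blocks[[key]]
    pid <- sub("_[0-9]+$", "", key)
    part <- ds$cohort$participants[ds$cohort$participants$id == pid, ]
    kin <- blk$kin
    ok <- blk$windows$lag_ms == 0 | blk$windows$comparison_phase == 2
    for (i in which(ok)) {
      w <- blk$windows[i, ]
      sl <- kin$t >= w$prep_start & kin$t < w$prep_end
      cm <- cycle_metrics(kin$t[sl], kin$angle_deg[sl],
                          center = part$amplitude_deg / 2)
      base[[length(base) + 1]] <- data.frame(
        participant_id = pid, amplitude_deg = cm$amplitude_deg,
        velocity_deg_s = cm$velocity_deg_s, interval_s = cm$interval_s)
    }
  }
  base <- stats::aggregate(cbind(amplitude_deg, velocity_deg_s, interval_s) ~
                             participant_id, do.call(rbind, base), mean)

  comp <- tab[apply_cmp_mask(tab, ds, TRUE), ]
  stnd <- tab[apply_cmp_mask(ds = ds, tab = tab, comparison = FALSE), ]
  key <- c("participant_id", "block", "trial")
  m <- merge(comp, stnd, by = key, suffixes = c("_c", "_s"))
  m <- merge(m, base, by = "participant_id")
  deltas <- data.frame(
    m[key], lag_ms = m$lag_ms_c, sound = m$sound_c,
    delta_amplitude = delta_index(m$amplitude_deg_c, m$amplitude_deg_s,
                                  m$amplitude_deg),
    delta_velocity = delta_index(m$velocity_deg_s_c, m$velocity_deg_s_s,
                                 m$velocity_deg_s),
    delta_interval = delta_index(m$interval_s_c, m$interval_s_s,
                                 m$interval_s))
  list(table = tab, deltas = deltas)
}

# rows of the metrics table belonging to the comparison (or standard) phase
apply_cmp_mask <- function(tab, ds, comparison) {
  tri <- ds$trials
  key <- paste(tab$participant_id, tab$block, tab$trial)
  tkey <- paste(tri$participant_id, tri$block, tri$trial)
  cmp_phase <- tri$comparison_phase[match(key, tkey)]
  if (comparison) tab$phase == cmp_phase else tab$phase != cmp_phase
}
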