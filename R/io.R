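#' Read a multichannel vital-sign record
#'
#' Reads a columnar CSV with header `t,ppg[,abp][,co]` sampled at a fixed
#' rate. The time column must be monotone and consistent with `fs` (median
#' spacing within 1%); NaN gaps of at most one second are bridged linearly
#' (and counted), longer gaps are an error.
#'
#' @param path CSV path.
#' @param fs Sampling rate, Hz; if `NULL`, taken from a JSON sidecar
#'   `<path>.meta.json` or inferred from the time column.
#' @param meta Optional metadata list (age, sex, height, weight); merged
#'   over any sidecar contents.
#' @return A tibble of class `vital_record` with attributes `fs`,
#'   `subject_id`, `meta`, `bridged_samples`.
#' @export
read_record <- function(path, fs = NULL, meta = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("t", "ppg") %in% names(df)))
    stop("record must have columns t and ppg")
  side <- paste0(path, ".meta.json")
  sm <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
  if (!is.null(meta)) sm[names(meta)] <- meta
  if (is.null(fs)) fs <- sm$fs
  dt <- diff(df$t)
  if (any(dt <= 0)) stop("time column is not strictly increasing")
  if (is.null(fs)) fs <- 1 / median(dt)
  if (abs(median(dt) - 1 / fs) > 0.01 / fs)
    stop(sprintf("time spacing (%.5g s) inconsistent with fs = %g Hz",
                 median(dt), fs))
  bridged <- 0L
  for (ch in intersect(c("ppg", "abp", "co"), names(df))) {
    v <- df[[ch]]
    if (anyNA(v)) {
      r <- rle(is.na(v))
      if (any(r$lengths[r$values] > fs))
        stop("NaN run longer than 1 s in channel ", ch)
      bridged <- bridged + sum(!is.finite(v))
      idx <- which(is.finite(v))
      df[[ch]] <- approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "fs") <- fs
  attr(out, "subject_id") <- if (!is.null(sm$subject_id)) sm$subject_id
  else sub("\\.csv$", "", basename(path))
  attr(out, "meta") <- sm
  attr(out, "bridged_samples") <- bridged
  class(out) <- c("vital_record", class(out))
  out
}

#' Write a record (and optional truth tracks) to CSV
#'
#' @param record Data frame with `t`, `ppg` and optionally `abp`, `co`
#'   (extra columns are dropped); a `wk4_record` also writes its per-beat
#'   ground-truth tracks to `<path>.truth.csv`.
#' @param path Output CSV path.
#' @param meta Optional metadata list written to `<path>.meta.json`
#'   (the record's `fs` is always included).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, meta = NULL) {
  cols <- intersect(c("t", "ppg", "abp", "co"), names(record))
  utils::write.csv(as.data.frame(record)[, cols], path, row.names = FALSE)
  side <- c(list(fs = attr(record, "fs")), meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"), auto_unbox = TRUE)
  truth <- attr(record, "truth")
  if (!is.null(truth))
    utils::write.csv(as.data.frame(truth), paste0(path, ".truth.csv"),
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Defaults follow the study conventions throughout: 50 Hz sampling, 100 s
#' windows with a 5 s hop (and 100-cycle beat windows), IRASA band
#' 0.5--10 Hz with factors 1.1--1.9, Higuchi `k_max = 10`, embedding
#' dimension 4, Granger alpha 0.05 with a 50 s maximum lag, and the four
#' beat-quality rules (PP < 15 mmHg, correlation < 0.8, interval outside
#' 0.5--1.5 s, window skewness < 0).
#'
#' @param fs Sampling rate, Hz.
#' @param window_s,hop_s Time-window geometry, s.
#' @param beats_per_window Cycles per beat-count window.
#' @param max_corrupt_s Corrupt time that disqualifies a window, s.
#' @param band IRASA band, Hz.
#' @param hset IRASA resampling factors.
#' @param complexity A [complexity_config()].
#' @param granger_alpha,granger_max_lag_s Granger test settings.
#' @param pp_min,corr_min,interval_range,skew_min Beat-quality thresholds.
#' @param measures Complexity measures computed per window.
#' @param seed Integer seed for the pipeline run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 50, window_s = 100, hop_s = 5,
                            beats_per_window = 100, max_corrupt_s = 10,
                            band = c(0.5, 10),
                            hset = seq(1.1, 1.9, by = 0.05),
                            complexity = complexity_config(),
                            granger_alpha = 0.05, granger_max_lag_s = 50,
                            pp_min = 15, corr_min = 0.8,
                            interval_range = c(0.5, 1.5), skew_min = 0,
                            measures = c("hfd", "kfd"),
                            seed = 1L) {
  structure(list(fs = fs, window_s = window_s, hop_s = hop_s,
                 beats_per_window = beats_per_window,
                 max_corrupt_s = max_corrupt_s, band = band, hset = hset,
                 complexity = complexity, granger_alpha = granger_alpha,
                 granger_max_lag_s = granger_max_lag_s, pp_min = pp_min,
                 corr_min = corr_min, interval_range = interval_range,
                 skew_min = skew_min, measures = measures,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Process one subject through the window-level pipeline
#'
#' Beat detection, detrending, beat features and quality rules, analysis
#' windows, per-window hemodynamics (means and fluctuation sigmas), IRASA
#' fractal fraction and power-law exponent per window, and the configured
#' complexity measures per window.
#'
#' @param record A record (e.g. [simulate_wk4()] or [read_record()]).
#' @param config A [pipeline_config()].
#' @return A list of class `subject_result`: `beats`, `windows`,
#'   `window_table` (one row per usable window with hemo + spectral +
#'   complexity columns), `sigma` (per-window fluctuations), and counts.
#' @export
process_subject <- function(record, config = pipeline_config()) {
  fs <- config$fs
  transient <- attr(record, "transient_s")
  if (is.null(transient)) transient <- 0
  feet <- detect_feet(record$ppg, fs)
  det <- detrend_ppg(record$ppg, feet)
  beats <- beat_features(record, feet, fs, det)
  beats <- flag_outlier_beats(beats, record$ppg, fs,
                              pp_min = config$pp_min,
                              corr_min = config$corr_min,
                              interval_range = config$interval_range,
                              skew_min = config$skew_min,
                              window_s = config$window_s,
                              hop_s = config$hop_s)
  # beats inside the startup transient are not used downstream
  beats$valid <- beats$valid & (beats$foot_idx - 1) / fs >= transient
  duration_s <- nrow(record) / fs
  windows <- make_windows(beats, duration_s, "time", fs,
                          window_s = config$window_s, hop_s = config$hop_s,
                          max_corrupt_s = config$max_corrupt_s)
  windows$usable <- windows$usable & windows$start_s >= transient
  track <- hemo_track(beats)
  sig <- windowed_sigma(track, windows,
                        cols = c("R", "C1", "SBP", "DBP", "MAP", "co"))
  usable <- windows[windows$usable, , drop = FALSE]
  spec_rows <- lapply(seq_len(nrow(usable)), function(k) {
    i0 <- floor(usable$start_s[k] * fs) + 1
    i1 <- min(nrow(record), floor(usable$end_s[k] * fs))
    sp <- irasa_split(record$ppg[i0:i1], fs, config$band, config$hset)
    pl <- tryCatch(fit_powerlaw(sp), error = function(e) NULL)
    tibble::tibble(window = usable$window[k],
                   fractal_pct = fractal_fraction(sp),
                   beta = if (is.null(pl)) NA_real_ else pl$beta,
                   beta_unc_pct = if (is.null(pl)) NA_real_ else
                     pl$rel_uncertainty_pct)
  })
  spectra <- dplyr::bind_rows(spec_rows)
  cx <- complexity_over_windows(record, windows, "raw", beats = beats,
                                fs = fs, config = config$complexity,
                                measures = config$measures)
  wt <- dplyr::left_join(spectra, cx, by = "window")
  wt <- dplyr::left_join(wt, sig, by = "window")
  wt <- dplyr::left_join(
    wt, dplyr::select(windows, "window", "start_s", "end_s"), by = "window")
  structure(list(beats = beats, windows = windows, window_table = wt,
                 sigma = sig,
                 n_beats = nrow(beats), n_valid = sum(beats$valid),
                 reject_counts = table(beats$reject_reason)),
            class = "subject_result")
}

#' Run the full pipeline over a set of records
#'
#' Processes each subject ([process_subject()]), runs the per-subject
#' Granger classification of the chosen hemodynamics--feature pair, and
#' assembles cohort-level tables. Failures in individual subjects are
#' caught and logged in the manifest; remaining subjects continue.
#'
#' @param records Named list of records (or of [sim_config()] objects,
#'   which are simulated on the fly).
#' @param config A [pipeline_config()].
#' @param granger_pair Character pair `c(hemo_col, feature_col)` of
#'   `window_table` columns (default SBP mean vs fractal fraction).
#' @param out_dir Optional directory; when given, per-subject and cohort
#'   CSVs plus a JSON run manifest are written.
#' @return A list of class `pipeline_result`: `subjects` (list of
#'   `subject_result`), `granger` (tibble), `cohort` (tibble of per-subject
#'   summaries), `manifest`.
#' @export
run_pipeline <- function(records, config = pipeline_config(),
                         granger_pair = c("mean_SBP", "fractal_pct"),
                         out_dir = NULL) {
  stopifnot(length(records) >= 1)
  ids <- names(records)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(records))
  set.seed(config$seed)
  subjects <- list(); granger <- list(); cohort <- list(); failures <- list()
  for (i in seq_along(records)) {
    id <- ids[i]
    res <- tryCatch({
      rec <- records[[i]]
      if (inherits(rec, "sim_config")) rec <- simulate_wk4(rec)
      process_subject(rec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      next
    }
    subjects[[id]] <- res
    wt <- res$window_table
    gv <- tryCatch(
      granger_classify(wt[[granger_pair[1]]], wt[[granger_pair[2]]],
                       max_lag_s = config$granger_max_lag_s,
                       hop_s = config$hop_s,
                       alpha = config$granger_alpha),
      error = function(e) NULL)
    if (!is.null(gv)) granger[[id]] <- dplyr::mutate(gv, subject_id = id,
                                                     .before = 1)
    cohort[[id]] <- tibble::tibble(
      subject_id = id,
      n_windows = sum(wt$window > 0),
      fractal_pct = median(wt$fractal_pct, na.rm = TRUE),
      hfd = if ("hfd" %in% names(wt)) median(wt$hfd, na.rm = TRUE) else NA,
      sigma_co = median(wt$sigma_co, na.rm = TRUE),
      sigma_SBP = median(wt$sigma_SBP, na.rm = TRUE),
      mean_SBP = median(wt$mean_SBP, na.rm = TRUE))
  }
  granger <- dplyr::bind_rows(granger)
  cohort <- dplyr::bind_rows(cohort)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ppgchaos")),
    seed = config$seed,
    n_subjects = length(records),
    n_processed = length(subjects),
    failures = failures,
    per_subject_counts = lapply(subjects, function(s)
      list(beats = s$n_beats, valid = s$n_valid))
  )
  out <- structure(list(subjects = subjects, granger = granger,
                        cohort = cohort, manifest = manifest,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(subjects)) {
      utils::write.csv(as.data.frame(subjects[[id]]$window_table),
                       file.path(out_dir, paste0(id, "_windows.csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(subjects[[id]]$beats),
                       file.path(out_dir, paste0(id, "_beats.csv")),
                       row.names = FALSE)
    }
    if (nrow(granger))
      utils::write.csv(as.data.frame(granger),
                       file.path(out_dir, "granger.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(cohort),
                     file.path(out_dir, "cohort.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Synthetic study cohort
#'
#' Builds the simulation configurations of a two-arm synthetic study:
#' every subject gets WK4 hemodynamic drift (OU fluctuation of R, C1 and
#' stroke volume) with a fluctuation magnitude that increases across
#' subjects, and power-law observation noise on the ppg channel whose
#' amplitude grows with that magnitude. In the *coupled* arm the noise
#' amplitude is additionally driven by the subject's lagged mean arterial
#' pressure, installing a hemodynamics-to-complexity causal pathway; the
#' *uncoupled* arm has amplitude-constant noise.
#'
#' @param n_subjects Number of subjects (default 20; half coupled).
#' @param duration_s Record length, s (default 900, i.e. 161
#'   analysis windows, leaving headroom over the 100-window Granger
#'   requirement when noisy windows are discarded).
#' @param seed Integer seed.
#' @param sigma_levels Range of relative OU fluctuation magnitudes spread
#'   across subjects (default 0.02--0.12).
#' @param noise_base Baseline power-law noise amplitude relative to the
#'   clean ppg standard deviation (default 0.08); each subject's amplitude
#'   is `noise_base + 1.2 * sigma_level`, so fractal power grows with the
#'   hemodynamic fluctuation by construction.
#' @param couple_gain MAP-modulation gain in the coupled arm (default 1.5).
#' @return A named list of [sim_config()] objects with a `coupled`
#'   attribute (logical vector).
#' @export
synth_cohort <- function(n_subjects = 20, duration_s = 900, seed = 1,
                         sigma_levels = c(0.02, 0.12), noise_base = 0.08,
                         couple_gain = 1.5) {
  set.seed(seed)
  coupled <- rep(c(TRUE, FALSE), length.out = n_subjects)
  sig <- seq(sigma_levels[1], sigma_levels[2], length.out = n_subjects)
  sig <- sample(sig) # decouple sigma level from arm assignment
  cfgs <- lapply(seq_len(n_subjects), function(i) {
    hr <- runif(1, 60, 90)
    sim_config(
      duration_s = duration_s, fs = 50,
      hr_bpm = hr, sv_ml = runif(1, 55, 80),
      R0 = runif(1, 0.9, 1.3), C1_0 = runif(1, 1.2, 1.8),
      C2_0 = 0.1, L0 = 0.02,
      fluct = list(R = c(sig[i], 60), C1 = c(sig[i], 45),
                   sv = c(sig[i], 30), hr = c(0.03, 20)),
      frac_noise = c(noise_base + 1.2 * sig[i], 1),
      frac_noise_relative = TRUE,
      meas_noise_sd = 2e-4,
      couple_noise_gain = if (coupled[i]) couple_gain else 0,
      couple_lag_s = 10,
      seed = sample.int(2^31 - 1, 1))
  })
  names(cfgs) <- sprintf("S%02d", seq_len(n_subjects))
  attr(cfgs, "coupled") <- coupled
  attr(cfgs, "sigma_level") <- sig
  cfgs
}
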