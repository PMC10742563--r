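#' Detect PPG foot points
#'
#' Locates one foot (pre-upstroke minimum) per cardiac cycle using a
#' slope-sum transform with a blockwise adaptive threshold and a 0.3 s
#' refractory period. The foot is placed at the last sample attaining the
#' local minimum (within a small tolerance) in the search span preceding
#' each threshold crossing, so flat diastolic baselines resolve to the
#' upstroke onset.
#'
#' @param ppg Numeric PPG sample series.
#' @param fs Sampling rate, Hz (>= 25).
#' @return Integer vector of 1-based foot indices, strictly increasing.
#' @export
detect_feet <- function(ppg, fs) {
  n <- length(ppg)
  stopifnot(fs >= 25, n >= 2 * fs)
  if (!is.finite(sd(ppg)) || sd(ppg) < 1e-12 * max(abs(mean(ppg)), 1e-12))
    stop("no beats detectable: signal is flat")
  # slope-sum function: running sum of positive slopes over ~0.13 s
  w <- max(2L, round(0.13 * fs))
  du <- pmax(diff(ppg), 0)
  ssf <- c(0, cumsum(du))
  ssf <- ssf - c(rep(0, w), head(ssf, -w)) # windowed sum
  # blockwise adaptive threshold (10 s blocks)
  blk <- pmin(ceiling(seq_len(n) / (10 * fs)), ceiling(n / (10 * fs)))
  thr_blk <- tapply(ssf, blk, function(v) 0.5 * quantile(v, 0.95))
  thr <- as.numeric(thr_blk[blk])
  above <- ssf >= thr & thr > 0
  crossings <- which(above & !c(FALSE, head(above, -1)))
  refr <- round(0.3 * fs)
  feet <- integer(0)
  last <- -refr
  search_back <- round(0.25 * fs)
  tol_amp <- 1e-3 * diff(range(ppg))
  for (cx in crossings) {
    if (cx - last < refr) next
    i0 <- max(1, cx - search_back)
    i1 <- min(n, cx + round(0.05 * fs))
    seg <- ppg[i0:i1]
    lo <- min(seg)
    foot <- i0 + max(which(seg <= lo + tol_amp)) - 1L
    if (length(feet) == 0 || foot - feet[length(feet)] >= refr) {
      feet <- c(feet, foot)
      last <- cx
    }
  }
  if (length(feet) < 1) stop("no beats detectable")
  unique(feet)
}

#' Detrend a PPG signal through its foot points
#'
#' The baseline (DC component) is the piecewise-linear interpolation through
#' the signal values at the foot points; the pulsatile (AC) component is the
#' residual, exactly zero at every foot. Samples before the first and after
#' the last foot carry `NA` in both outputs.
#'
#' @param ppg Numeric PPG series.
#' @param feet Integer foot indices (>= 2 of them).
#' @return A tibble with columns `pulsatile` and `baseline`, same length as
#'   `ppg`.
#' @export
detrend_ppg <- function(ppg, feet) {
  stopifnot(length(feet) >= 2)
  n <- length(ppg)
  baseline <- rep(NA_real_, n)
  idx <- feet[1]:feet[length(feet)]
  baseline[idx] <- approx(feet, ppg[feet], xout = idx)$y
  tibble::tibble(pulsatile = ppg - baseline, baseline = baseline)
}

# Pearson correlation of two beat waveforms after resampling each to npts
beat_corr <- function(a, b, npts = 50) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  ra <- approx(seq_along(a), a, n = npts)$y
  rb <- approx(seq_along(b), b, n = npts)$y
  if (sd(ra) == 0 || sd(rb) == 0) return(NA_real_)
  cor(ra, rb)
}

#' Per-beat features
#'
#' Builds the beat table: timing, PPG AC/DC, arterial pressures (when an
#' `abp` channel is present), mean cardiac output (when `co` is present) and
#' the PPG--BP waveform correlation used by the quality rules.
#'
#' @param record A data frame with columns `ppg` and optionally `abp`, `co`
#'   (e.g. a [simulate_wk4()] record or [read_record()] output).
#' @param feet Foot indices from [detect_feet()].
#' @param fs Sampling rate in Hz; defaults to the record's `fs` attribute.
#' @param detrended Optional output of [detrend_ppg()]; computed if missing.
#' @return A tibble with one row per beat: `beat`, `foot_idx`,
#'   `next_foot_idx`, `interval_s`, `AC`, `DC`, and (channel permitting)
#'   `SBP`, `DBP`, `MAP`, `PP`, `co_mean`, `ppg_bp_corr`.
#' @export
beat_features <- function(record, feet, fs = attr(record, "fs"),
                          detrended = NULL) {
  stopifnot(!is.null(fs), length(feet) >= 2)
  if (is.null(detrended)) detrended <- detrend_ppg(record$ppg, feet)
  nb <- length(feet) - 1
  has_abp <- "abp" %in% names(record) && !all(is.na(record$abp))
  has_co <- "co" %in% names(record) && !all(is.na(record$co))
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    i0 <- feet[b]; i1 <- feet[b + 1]
    span <- i0:(i1 - 1)
    pulse <- detrended$pulsatile[span]
    row <- list(
      beat = b, foot_idx = i0, next_foot_idx = i1,
      interval_s = (i1 - i0) / fs,
      AC = max(pulse) - min(pulse),
      DC = mean(detrended$baseline[span])
    )
    if (has_abp) {
      bp <- record$abp[span]
      row$SBP <- max(bp); row$DBP <- min(bp)
      row$MAP <- mean(bp); row$PP <- row$SBP - row$DBP
      row$ppg_bp_corr <- beat_corr(record$ppg[span], bp)
    }
    if (has_co) row$co_mean <- mean(record$co[span])
    out[[b]] <- tibble::as_tibble(row)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "fs") <- fs
  res
}

# Fisher-Pearson (biased, g1) skewness
skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Flag outlier beats
#'
#' Applies the four per-cardiac-cycle quality rules, in the fixed order
#' PP_LOW, CORR_LOW, INTERVAL, SKEW; a beat failing several rules carries
#' the first matching reason:
#' * `PP_LOW`: pulse pressure < 15 mmHg;
#' * `CORR_LOW`: PPG--BP waveform correlation < 0.8;
#' * `INTERVAL`: beat interval outside 0.5--1.5 s;
#' * `SKEW`: the beat lies in an analysis window whose raw-PPG skewness is
#'   negative (all beats of such a window are flagged).
#'
#' Rules whose inputs are absent (no `abp` channel) are skipped.
#'
#' @param beats Beat table from [beat_features()].
#' @param ppg Raw PPG series (needed for the skewness rule); optional.
#' @param fs Sampling rate, Hz.
#' @param pp_min,corr_min,interval_range,skew_min Rule thresholds; defaults
#'   are 15 mmHg, 0.8, `c(0.5, 1.5)` s and 0.
#' @param window_s,hop_s Analysis window geometry for the skewness rule.
#' @return The beat table with added logical `valid` and factor
#'   `reject_reason` (`NONE`, `PP_LOW`, `CORR_LOW`, `INTERVAL`, `SKEW`).
#' @export
flag_outlier_beats <- function(beats, ppg = NULL, fs = attr(beats, "fs"),
                               pp_min = 15, corr_min = 0.8,
                               interval_range = c(0.5, 1.5), skew_min = 0,
                               window_s = 100, hop_s = 5) {
  nb <- nrow(beats)
  reason <- rep(NA_character_, nb)
  hit <- function(cond) is.na(reason) & !is.na(cond) & cond
  if ("PP" %in% names(beats)) reason[hit(beats$PP < pp_min)] <- "PP_LOW"
  if ("ppg_bp_corr" %in% names(beats))
    reason[hit(beats$ppg_bp_corr < corr_min)] <- "CORR_LOW"
  reason[hit(beats$interval_s < interval_range[1] |
               beats$interval_s > interval_range[2])] <- "INTERVAL"
  if (!is.null(ppg) && !is.null(fs)) {
    n <- length(ppg)
    starts <- seq(0, max(0, n / fs - window_s), by = hop_s)
    bad <- rep(FALSE, nb)
    beat_t0 <- (beats$foot_idx - 1) / fs
    beat_t1 <- (beats$next_foot_idx - 1) / fs
    for (s in starts) {
      i0 <- floor(s * fs) + 1
      i1 <- min(n, floor((s + window_s) * fs))
      if (skewness(ppg[i0:i1]) < skew_min)
        bad <- bad | (beat_t1 > s & beat_t0 < s + window_s)
    }
    reason[hit(bad)] <- "SKEW"
  }
  beats$valid <- is.na(reason)
  beats$reject_reason <- factor(
    ifelse(is.na(reason), "NONE", reason),
    levels = c("NONE", "PP_LOW", "CORR_LOW", "INTERVAL", "SKEW"))
  beats
}

#' Build analysis windows
#'
#' Two schemes: `"time"` gives fixed 100 s windows stepped by a 5 s hop
#' (half-open `[start, start + 100)`); a window is unusable when more than
#' `max_corrupt_s` seconds of it are invalid beats or not covered by any
#' beat. `"beats"` chunks the valid beats, in temporal order, into disjoint
#' blocks of `n_beats` cycles.
#'
#' @param beats Flagged beat table from [flag_outlier_beats()].
#' @param duration_s Record duration in seconds.
#' @param scheme `"time"` or `"beats"`.
#' @param fs Sampling rate, Hz.
#' @param window_s,hop_s Time-window length and hop (defaults 100 s, 5 s).
#' @param max_corrupt_s Maximum tolerated corrupt time per window (10 s).
#' @param n_beats Valid cycles per window for the `"beats"` scheme (100).
#' @return A tibble of class `ppg_windows`: `window`, `start_s`, `end_s`,
#'   `first_beat`, `last_beat`, `n_valid`, `corrupt_s`, `usable`, with a
#'   `scheme` attribute.
#' @export
make_windows <- function(beats, duration_s, scheme = c("time", "beats"),
                         fs = attr(beats, "fs"),
                         window_s = 100, hop_s = 5, max_corrupt_s = 10,
                         n_beats = 100) {
  scheme <- match.arg(scheme)
  if (!"valid" %in% names(beats)) beats$valid <- TRUE
  beat_t0 <- (beats$foot_idx - 1) / fs
  beat_t1 <- (beats$next_foot_idx - 1) / fs
  if (scheme == "time") {
    if (duration_s < window_s) {
      warning("record shorter than one window")
      return(empty_windows(scheme))
    }
    starts <- seq(0, duration_s - window_s, by = hop_s)
    rows <- lapply(seq_along(starts), function(k) {
      s <- starts[k]; e <- s + window_s
      ov <- pmax(0, pmin(beat_t1, e) - pmax(beat_t0, s))
      covered_valid <- sum(ov[beats$valid])
      corrupt <- window_s - covered_valid # invalid beats + uncovered signal
      inw <- which(ov > 0)
      tibble::tibble(window = k, start_s = s, end_s = e,
                     first_beat = if (length(inw)) min(inw) else NA_integer_,
                     last_beat = if (length(inw)) max(inw) else NA_integer_,
                     n_valid = sum(beats$valid[inw]),
                     corrupt_s = corrupt,
                     usable = corrupt <= max_corrupt_s)
    })
    out <- dplyr::bind_rows(rows)
  } else {
    vidx <- which(beats$valid)
    nw <- floor(length(vidx) / n_beats)
    if (nw == 0) {
      warning("record has fewer than one window of valid beats")
      return(empty_windows(scheme))
    }
    rows <- lapply(seq_len(nw), function(k) {
      sel <- vidx[((k - 1) * n_beats + 1):(k * n_beats)]
      tibble::tibble(window = k,
                     start_s = beat_t0[sel[1]],
                     end_s = beat_t1[sel[n_beats]],
                     first_beat = sel[1], last_beat = sel[n_beats],
                     n_valid = n_beats, corrupt_s = 0, usable = TRUE)
    })
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "scheme") <- scheme
  attr(out, "fs") <- fs
  attr(out, "window_s") <- window_s
  attr(out, "hop_s") <- hop_s
  class(out) <- c("ppg_windows", class(out))
  out
}

empty_windows <- function(scheme) {
  out <- tibble::tibble(window = integer(), start_s = numeric(),
                        end_s = numeric(), first_beat = integer(),
                        last_beat = integer(), n_valid = integer(),
                        corrupt_s = numeric(), usable = logical())
  attr(out, "scheme") <- scheme
  class(out) <- c("ppg_windows", class(out))
  out
}

#' Subject inclusion filter
#'
#' Inclusion requires age over 18 years, weight over 40 kg, height over
#' 145 cm and a body-mass index between 16 and 35 kg/m^2; subjects with a
#' window-median systolic pressure below 80 mmHg (suspected excessive blood
#' loss) are excluded.
#'
#' @param meta A list or one-row data frame with `age` (years), `weight`
#'   (kg), `height` (cm); `sex` is carried but not used.
#' @param sbp_window_medians Optional numeric vector of per-window SBP
#'   medians (mmHg).
#' @return `TRUE` if the subject is included.
#' @export
filter_subject <- function(meta, sbp_window_medians = NULL) {
  need <- c("age", "weight", "height")
  miss <- need[!need %in% names(meta) |
                 vapply(need, function(f) is.null(meta[[f]]) ||
                          is.na(meta[[f]]), logical(1))]
  if (length(miss))
    stop("missing metadata field(s): ", paste(miss, collapse = ", "))
  bmi <- meta$weight / (meta$height / 100)^2
  ok <- meta$age > 18 && meta$weight > 40 && meta$height > 145 &&
    bmi >= 16 && bmi <= 35
  if (ok && !is.null(sbp_window_medians) &&
      any(sbp_window_medians < 80, na.rm = TRUE)) ok <- FALSE
  ok
}
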