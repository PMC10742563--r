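#' Morphological features of one PPG beat
#'
#' Computes the standard contour features of a single detrended beat
#' waveform (foot to next foot):
#' * `AREA`: area under the waveform after normalizing amplitude and time
#'   to the unit square (trapezoidal rule);
#' * `SPMEAN`, `SPVAR`: mean and standard deviation of the upstroke slope
#'   (first difference times `fs`) over the systolic limb (foot to the
#'   global maximum);
#' * `DPMEAN`, `DPVAR`: likewise over the diastolic limb (peak to end);
#' * `b_a`: ratio of the early negative peak (`b`, the deepest minimum
#'   following the a-wave) to the early positive peak (`a`, the largest
#'   maximum) of the second derivative (acceleration pulse), both restricted
#'   to the first 40% of the beat; the second derivative is taken by
#'   central differences after 5-point moving-average smoothing.
#'
#' @param x Numeric beat waveform (pulsatile samples, >= 10 of them).
#' @param fs Sampling rate, Hz.
#' @return A one-row tibble with `AREA`, `SPMEAN`, `SPVAR`, `DPMEAN`,
#'   `DPVAR`, `b_a` and a logical `morph_valid` (FALSE when the systolic
#'   peak falls on the beat boundary, which leaves a limb empty).
#' @examples
#' beat <- sin(pi * seq(0, 1, length.out = 50)) # half-sine, AREA ~ 2/pi
#' morph_features(beat, fs = 50)
#' @export
morph_features <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 10, fs > 0)
  bad <- tibble::tibble(AREA = NA_real_, SPMEAN = NA_real_,
                        SPVAR = NA_real_, DPMEAN = NA_real_,
                        DPVAR = NA_real_, b_a = NA_real_,
                        morph_valid = FALSE)
  pk <- which.max(x)
  if (pk <= 1 || pk >= n) return(bad)
  rng <- diff(range(x))
  if (rng == 0) return(bad)

  xn <- (x - min(x)) / rng # amplitude to [0, 1]
  u <- seq(0, 1, length.out = n) # time to [0, 1]
  AREA <- sum(diff(u) * (head(xn, -1) + tail(xn, -1)) / 2)

  slope <- diff(x) * fs
  up <- slope[seq_len(pk - 1)]
  down <- slope[pk:(n - 1)]
  SPMEAN <- mean(up)
  SPVAR <- if (length(up) >= 2) sd(up) else 0
  DPMEAN <- mean(down)
  DPVAR <- if (length(down) >= 2) sd(down) else 0

  # acceleration pulse: smooth, then central second difference
  sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  d2 <- c(NA, diff(diff(as.numeric(sm))), NA) * fs^2
  lim <- max(3, floor(0.4 * n))
  d2e <- d2[2:lim]
  b_a <- NA_real_
  a_idx <- which.max(d2e)
  if (length(a_idx) && is.finite(d2e[a_idx]) && d2e[a_idx] > 0 &&
      a_idx < length(d2e)) {
    b_idx <- a_idx + which.min(d2e[(a_idx + 1):length(d2e)])
    if (is.finite(d2e[b_idx]) && d2e[b_idx] < 0)
      b_a <- d2e[b_idx] / d2e[a_idx]
  }
  tibble::tibble(AREA = AREA, SPMEAN = SPMEAN, SPVAR = SPVAR,
                 DPMEAN = DPMEAN, DPVAR = DPVAR, b_a = b_a,
                 morph_valid = TRUE)
}

#' Morphological features for every beat of a record
#'
#' Applies [morph_features()] to each beat of a flagged beat table and
#' appends the resulting columns.
#'
#' @param beats Beat table from [beat_features()].
#' @param pulsatile Detrended pulsatile series (from [detrend_ppg()]).
#' @param fs Sampling rate, Hz.
#' @return `beats` with the morphology columns appended.
#' @export
beat_morphology <- function(beats, pulsatile, fs = attr(beats, "fs")) {
  na_row <- tibble::tibble(AREA = NA_real_, SPMEAN = NA_real_,
                           SPVAR = NA_real_, DPMEAN = NA_real_,
                           DPVAR = NA_real_, b_a = NA_real_,
                           morph_valid = FALSE)
  rows <- lapply(seq_len(nrow(beats)), function(b) {
    span <- beats$foot_idx[b]:(beats$next_foot_idx[b] - 1)
    w <- pulsatile[span]
    if (length(w) < 10 || anyNA(w)) return(na_row)
    morph_features(w, fs)
  })
  dplyr::bind_cols(beats, dplyr::bind_rows(rows))
}
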