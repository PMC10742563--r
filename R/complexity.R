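#' Complexity configuration
#'
#' Defaults for the nonlinear measures: `k_max = 10` Higuchi scales,
#' embedding dimension `m = 4`, tolerance `r = 0.2 * sd` per window, fuzzy
#' membership gradient 2, recurrence threshold at 10% of the attractor
#' diameter with minimum diagonal length 2, and unit embedding delay.
#'
#' @param k_max Maximum Higuchi segment count (>= 2).
#' @param m Embedding dimension for the entropies and RQA (>= 1).
#' @param r_frac Tolerance as a fraction of the window standard deviation.
#' @param fuzz_gradient Fuzzy-membership exponent.
#' @param rqa_eps_frac Recurrence threshold as a fraction of the attractor
#'   diameter.
#' @param rqa_lmin Minimum diagonal line length.
#' @param tau Embedding delay in samples.
#' @return A list of class `complexity_config`.
#' @export
complexity_config <- function(k_max = 10, m = 4, r_frac = 0.2,
                              fuzz_gradient = 2, rqa_eps_frac = 0.1,
                              rqa_lmin = 2, tau = 1) {
  stopifnot(k_max >= 2, m >= 1, r_frac > 0, r_frac < 1, tau >= 1,
            rqa_lmin >= 1)
  structure(list(k_max = k_max, m = m, r_frac = r_frac,
                 fuzz_gradient = fuzz_gradient,
                 rqa_eps_frac = rqa_eps_frac, rqa_lmin = rqa_lmin,
                 tau = tau),
            class = "complexity_config")
}

#' Higuchi fractal dimension
#'
#' Normalized curve lengths `L(k)` are computed for scales `k = 1..k_max`
#' and all offsets; the dimension is the OLS slope of `ln L(k)` on
#' `ln(1/k)`. The relative fit uncertainty (percent, from the coefficient
#' variance--covariance matrix) is attached as attribute
#' `rel_uncertainty_pct`.
#'
#' @param x Numeric series of length >= 10 * k_max.
#' @param k_max Maximum segment count (default 10).
#' @return The fractal dimension (~1 for a smooth line, ~2 for white
#'   noise), with attributes `rel_uncertainty_pct` and `flag` (set to
#'   "degenerate" for a constant series, which returns 1).
#' @export
hfd <- function(x, k_max = 10) {
  n <- length(x)
  stopifnot(n >= 10 * k_max)
  if (diff(range(x)) == 0) {
    return(structure(1, rel_uncertainty_pct = NA_real_, flag = "degenerate"))
  }
  Lk <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      idx <- seq(m, n, by = k)
      ni <- length(idx) - 1
      if (ni < 1) return(NA_real_)
      (sum(abs(diff(x[idx]))) * (n - 1) / (ni * k)) / k
    }, numeric(1))
    mean(Lm, na.rm = TRUE)
  }, numeric(1))
  fit <- lm(log(Lk) ~ log(1 / seq_len(k_max)))
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(sqrt(vcov(fit)[2, 2]))
  structure(slope, rel_uncertainty_pct = 100 * se / abs(slope), flag = "ok")
}

#' Katz fractal dimension
#'
#' `KFD = log10(n) / (log10(n) + log10(d / L))` with `L` the total polyline
#' length `sum(|diff(x)|)`, `d` the maximum distance from the first point
#' `max(|x - x[1]|)`, and `n` the number of steps. Waveform-only distances
#' make the measure scale-invariant; a straight line gives exactly 1.
#'
#' @param x Numeric series of length >= 3.
#' @return The dimension (>= 1), with attribute `flag` ("degenerate" when
#'   all points coincide, returning 1).
#' @export
kfd <- function(x) {
  stopifnot(length(x) >= 3)
  L <- sum(abs(diff(x)))
  d <- max(abs(x - x[1]))
  n <- length(x) - 1
  if (d == 0 || L == 0) return(structure(1, flag = "degenerate"))
  structure(log10(n) / (log10(n) + log10(d / L)), flag = "ok")
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` and `A` count template pairs (self-matches
#' excluded) within Chebyshev tolerance `r_abs` at lengths `m` and `m + 1`.
#' When no `(m+1)`-matches exist the value is capped at `ln(B) + ln(2)` and
#' flagged.
#'
#' @param x Numeric series (length >= 4 * m).
#' @param m Template length (default 4).
#' @param r_abs Absolute tolerance (> 0), typically `0.2 * sd(x)`.
#' @return Entropy in nats with attribute `flag` ("no_match" when capped,
#'   "degenerate" when no m-matches exist at all, returning NA).
#' @export
sampen <- function(x, m = 4, r_abs) {
  stopifnot(length(x) >= 4 * m, r_abs > 0)
  cnt <- .sampen_counts(as.numeric(x), as.integer(m), r_abs)
  B <- cnt[["B"]]; A <- cnt[["A"]]
  if (B == 0) return(structure(NA_real_, flag = "degenerate"))
  if (A == 0) return(structure(log(B) + log(2), flag = "no_match"))
  structure(-log(A / B), flag = "ok")
}

#' Approximate entropy
#'
#' `ApEn = Phi_m - Phi_{m+1}` with `Phi_m` the mean log fraction of
#' templates (self-matches included) within tolerance under the Chebyshev
#' distance.
#'
#' @inheritParams sampen
#' @return Entropy in nats.
#' @export
apen <- function(x, m = 4, r_abs) {
  stopifnot(length(x) >= 4 * m, r_abs > 0)
  x <- as.numeric(x)
  .apen_phi(x, as.integer(m), r_abs) - .apen_phi(x, as.integer(m + 1), r_abs)
}

#' Fuzzy entropy
#'
#' Templates are mean-subtracted and matched with the fuzzy membership
#' `exp(-(d/r)^gradient)` under the Chebyshev distance;
#' `FuzzEn = ln(phi_m) - ln(phi_{m+1})`.
#'
#' @inheritParams sampen
#' @param gradient Membership exponent (default 2).
#' @return Entropy in nats.
#' @export
fuzzen <- function(x, m = 4, r_abs, gradient = 2) {
  stopifnot(length(x) >= 4 * m, r_abs > 0)
  x <- as.numeric(x)
  log(.fuzzen_phi(x, as.integer(m), r_abs, gradient)) -
    log(.fuzzen_phi(x, as.integer(m + 1), r_abs, gradient))
}

#' Recurrence diagonal-line entropy (RQA ENTR)
#'
#' Delay-embeds the series, thresholds the Chebyshev recurrence matrix at
#' `eps_frac` times the attractor diameter, and returns the Shannon entropy
#' (nats) of the distribution of diagonal line lengths `>= lmin`, excluding
#' the main diagonal.
#'
#' @param x Numeric series (>= 50 points after embedding).
#' @param m Embedding dimension (default 4).
#' @param tau Embedding delay in samples (default 1).
#' @param eps_frac Recurrence threshold as a fraction of the attractor
#'   diameter (default 0.1).
#' @param lmin Minimum line length (default 2).
#' @return Entropy in nats with attribute `flag` ("no_lines" when no
#'   diagonal reaches `lmin`, returning 0).
#' @export
rqa_entr <- function(x, m = 4, tau = 1, eps_frac = 0.1, lmin = 2) {
  x <- as.numeric(x)
  ne <- length(x) - (m - 1) * tau
  stopifnot(ne >= 50)
  diam <- .embed_diameter(x, as.integer(m), as.integer(tau))
  if (diam == 0) return(structure(0, flag = "degenerate"))
  hist <- .rqa_diag_hist(x, as.integer(m), as.integer(tau), eps_frac * diam)
  if (length(hist) >= lmin) hist <- hist[lmin:length(hist)] else hist <- integer(0)
  tot <- sum(hist)
  if (tot == 0) return(structure(0, flag = "no_lines"))
  p <- hist[hist > 0] / tot
  structure(-sum(p * log(p)), flag = "ok")
}

#' False-nearest-neighbour embedding dimension
#'
#' Kennel's criterion: for each candidate dimension the fraction of nearest
#' neighbours that become distant when the embedding is extended by one
#' coordinate (ratio test `rtol`, absolute test `atol`). Returns the
#' smallest dimension with a false-neighbour fraction below 5%, or the
#' argmin (flagged) if the fraction never drops below it.
#'
#' @param x Numeric series (length >= 500).
#' @param max_m Largest dimension tried (default 10).
#' @param tau Embedding delay (default 1).
#' @param rtol,atol Kennel tolerances (defaults 10 and 2).
#' @return Integer dimension with attributes `fractions` and `flag`.
#' @export
fnn_dimension <- function(x, max_m = 10, tau = 1, rtol = 10, atol = 2) {
  stopifnot(length(x) >= 500)
  fr <- .fnn_fractions(as.numeric(x), as.integer(max_m), as.integer(tau),
                       rtol, atol)
  below <- which(fr < 0.05)
  if (length(below)) {
    structure(below[1], fractions = fr, flag = "ok")
  } else {
    structure(which.min(fr), fractions = fr, flag = "never_below")
  }
}

#' Embedding delay from the autocorrelation function
#'
#' The standard heuristic for delay embeddings: the first lag at which the
#' sample autocorrelation crosses zero (capped at `max_lag`).
#'
#' @param x Numeric series.
#' @param max_lag Largest lag considered (default `length(x) %/% 4`).
#' @return Integer delay in samples (>= 1).
#' @export
embedding_delay <- function(x, max_lag = length(x) %/% 4) {
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  k <- which(a <= 0)
  if (length(k)) max(1L, k[1]) else as.integer(max_lag)
}

#' HRV low-frequency to high-frequency power ratio
#'
#' Beat intervals are interpolated onto a uniform 4 Hz grid (cubic spline)
#' and Welch power in the LF (0.04--0.15 Hz) and HF (0.15--0.40 Hz) bands
#' is integrated; the ratio LF/HF indexes sympathovagal balance.
#'
#' @param intervals Beat-to-beat intervals, s.
#' @param times Beat onset times, s (same length).
#' @return The LF/HF ratio (`NA` when HF power is zero).
#' @export
lf_hf <- function(intervals, times) {
  stopifnot(length(intervals) == length(times),
            max(times) - min(times) >= 60)
  fs_i <- 4
  grid <- seq(min(times), max(times), by = 1 / fs_i)
  y <- spline(times, intervals, xout = grid)$y
  w <- welch_psd(y, fs_i, seg_s = min(120, length(grid) / fs_i))
  band_power <- function(lo, hi) {
    sel <- w$freq >= lo & w$freq <= hi
    if (sum(sel) < 2) return(0)
    sum(diff(w$freq[sel]) * (head(w$psd[sel], -1) + tail(w$psd[sel], -1)) / 2)
  }
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, 0.40)
  if (hf <= 0) return(NA_real_)
  lf / hf
}

#' Roessler attractor x-coordinate
#'
#' Reference chaotic series (a = 0.2, b = 0.2, c = 5.7, dt = 0.1 after a
#' discarded transient), used to validate the embedding-dimension
#' estimator.
#'
#' @param n Number of samples.
#' @param dt Sampling step of the returned series.
#' @param seed Seed for the randomized initial condition.
#' @return Numeric vector of length `n`.
#' @export
roessler_x <- function(n, dt = 0.1, seed = 1) {
  set.seed(seed)
  y0 <- c(x = runif(1, -1, 1), y = runif(1, -1, 1), z = 0)
  rhs <- function(t, y, p)
    list(c(-y[2] - y[3], y[1] + 0.2 * y[2], 0.2 + y[3] * (y[1] - 5.7)))
  times <- seq(0, (n + 500) * dt, by = dt)
  sol <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-8)
  as.numeric(sol[(501):(500 + n), "x"])
}

#' Complexity measures over analysis windows
#'
#' Applies the configured measures to one of the sampling schemes within
#' each usable window:
#' * `"raw"`: the 50 Hz PPG waveform over time windows;
#' * `"wavelet"`: each Morse wavelet component over time windows;
#' * `"ac"` / `"dc"`: the per-beat pulsatile amplitude / baseline series
#'   over beat-count windows (beat index as abscissa).
#'
#' The entropy tolerance `r = r_frac * sd` is recomputed per window (and
#' per component). Windows flagged unusable are skipped.
#'
#' @param record Data frame with a `ppg` column (for `"raw"`/`"wavelet"`).
#' @param windows A [make_windows()] table (time scheme for
#'   `"raw"`/`"wavelet"`, beat scheme for `"ac"`/`"dc"`).
#' @param scheme One of `"raw"`, `"wavelet"`, `"ac"`, `"dc"`.
#' @param beats Flagged beat table (required for `"ac"`/`"dc"` and for
#'   `lf_hf`).
#' @param fs Sampling rate, Hz.
#' @param config A [complexity_config()].
#' @param measures Character subset of `c("hfd", "kfd", "sampen", "apen",
#'   "fuzzen", "rqa_entr", "lf_hf")`.
#' @param wavelet_freqs Center frequencies for the wavelet scheme.
#' @return A tibble: `window`, `scheme`, (`wavelet_freq`,) one column per
#'   measure, `degenerate` flag.
#' @export
complexity_over_windows <- function(record, windows,
                                    scheme = c("raw", "wavelet", "ac", "dc"),
                                    beats = NULL,
                                    fs = attr(record, "fs"),
                                    config = complexity_config(),
                                    measures = c("hfd", "kfd", "sampen",
                                                 "apen", "fuzzen",
                                                 "rqa_entr"),
                                    wavelet_freqs = c(11.63, 8.23, 5.82,
                                                      4.11, 2.91, 2.06,
                                                      1.45)) {
  scheme <- match.arg(scheme)
  cfgm <- config$m
  eval_series <- function(x) {
    out <- list()
    x <- x[is.finite(x)]
    degen <- length(x) < max(10 * config$k_max, 4 * cfgm + 2) ||
      diff(range(x)) == 0 || sd(x) == 0
    r_abs <- if (!degen) config$r_frac * sd(x) else 1
    for (ms in measures) {
      out[[ms]] <- if (degen && !ms %in% c("hfd", "kfd")) NA_real_ else
        switch(ms,
               hfd = as.numeric(hfd(x, config$k_max)),
               kfd = as.numeric(kfd(x)),
               sampen = as.numeric(sampen(x, cfgm, r_abs)),
               apen = as.numeric(apen(x, cfgm, r_abs)),
               fuzzen = as.numeric(fuzzen(x, cfgm, r_abs,
                                          config$fuzz_gradient)),
               rqa_entr = as.numeric(rqa_entr(x, cfgm, config$tau,
                                              config$rqa_eps_frac,
                                              config$rqa_lmin)),
               NA_real_)
    }
    out$degenerate <- degen
    out
  }
  usable <- windows[windows$usable, , drop = FALSE]
  rows <- list()
  if (scheme %in% c("raw", "wavelet")) {
    bank <- if (scheme == "wavelet")
      wavelet_components(record$ppg, fs, wavelet_freqs) else NULL
    for (k in seq_len(nrow(usable))) {
      i0 <- floor(usable$start_s[k] * fs) + 1
      i1 <- min(nrow(record), floor(usable$end_s[k] * fs))
      if (scheme == "raw") {
        res <- eval_series(record$ppg[i0:i1])
        if ("lf_hf" %in% measures && !is.null(beats)) {
          bsel <- beats$valid &
            (beats$foot_idx - 1) / fs >= usable$start_s[k] &
            (beats$foot_idx - 1) / fs < usable$end_s[k]
          res$lf_hf <- if (sum(bsel) >= 3 &&
                           diff(range((beats$foot_idx[bsel] - 1) / fs)) >= 60)
            lf_hf(beats$interval_s[bsel], (beats$foot_idx[bsel] - 1) / fs)
          else NA_real_
        }
        rows[[length(rows) + 1]] <- tibble::as_tibble(
          c(list(window = usable$window[k], scheme = scheme), res))
      } else {
        for (fc in names(bank)) {
          res <- eval_series(bank[[fc]][i0:i1])
          rows[[length(rows) + 1]] <- tibble::as_tibble(
            c(list(window = usable$window[k], scheme = scheme,
                   wavelet_freq = as.numeric(sub("^w", "", fc))), res))
        }
      }
    }
  } else {
    stopifnot(!is.null(beats))
    series <- if (scheme == "ac") beats$AC else beats$DC
    for (k in seq_len(nrow(usable))) {
      sel <- seq(usable$first_beat[k], usable$last_beat[k])
      sel <- sel[beats$valid[sel]]
      res <- eval_series(series[sel])
      rows[[length(rows) + 1]] <- tibble::as_tibble(
        c(list(window = usable$window[k], scheme = scheme), res))
    }
  }
  dplyr::bind_rows(rows)
}
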