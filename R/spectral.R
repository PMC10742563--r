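#' Welch power spectral density
#'
#' Hann-tapered Welch estimator with 50% segment overlap, normalized so
#' that the integral of the one-sided density over frequency equals the
#' signal variance (signal-units^2/Hz).
#'
#' @param x Numeric series (mean is removed).
#' @param fs Sampling rate, Hz.
#' @param seg_s Segment length in seconds (default 10).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `freq` (Hz, excluding DC) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_s = 10, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, max(8, round(seg_s * fs)))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, n - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1)) # Hann
  U <- sum(win^2)
  x <- x - mean(x)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * win
    acc <- acc + Mod(fft(seg))^2
  }
  pxx <- acc / (length(starts) * U * fs)
  nf <- floor(nseg / 2)
  psd <- 2 * pxx[2:(nf + 1)]
  if (nseg %% 2 == 0) psd[nf] <- psd[nf] / 2 # Nyquist bin is not doubled
  tibble::tibble(freq = (1:nf) * fs / nseg, psd = psd)
}

#' IRASA separation of fractal and oscillatory spectral power
#'
#' Irregular-resampling auto-spectral analysis: the signal is resampled by
#' each non-integer factor `h` and its reciprocal (polyphase, anti-aliased),
#' the Welch auto-spectra of each pair are combined by their geometric mean
#' on the common frequency grid, and the median across `h` is taken as the
#' fractal (power-law) component. Oscillatory peaks are displaced by a
#' resampling-dependent offset and cancel in the median; the fractal
#' component is invariant. The oscillatory PSD is the (possibly pointwise
#' negative) remainder `total - fractal`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz (or cycles/beat for per-beat series, with
#'   `fs = 1`).
#' @param band Frequency band `c(f_lo, f_hi)` to retain, Hz.
#' @param hset Resampling factors, all > 1 (default `seq(1.1, 1.9, 0.05)`).
#' @param seg_s Welch segment length, s (default 10).
#' @return A tibble of class `ppg_spectral_split` with columns `freq`,
#'   `psd_total`, `psd_fractal`, `psd_oscillatory`, plus `band` and `hset`
#'   attributes.
#' @export
irasa_split <- function(x, fs, band = c(0.5, 10),
                        hset = seq(1.1, 1.9, by = 0.05), seg_s = 10) {
  stopifnot(all(hset > 1), band[1] > 0, band[2] > band[1])
  feasible <- fs / 2 / max(hset)
  if (band[2] > feasible)
    stop(sprintf(
      "band upper edge %.3g Hz exceeds the feasible limit %.3g Hz (Nyquist/max(hset))",
      band[2], feasible))
  if (length(x) < 2 * fs / band[1])
    stop("series too short for the requested lower band edge")
  total <- welch_psd(x, fs, seg_s)
  grid <- total$freq
  frac_h <- matrix(NA_real_, nrow = length(grid), ncol = length(hset))
  for (k in seq_along(hset)) {
    h <- hset[k]
    p <- round(h * 20); q <- 20
    g <- gcd2(p, q); p <- p / g; q <- q / g
    up <- signal::resample(x, p, q)
    dn <- signal::resample(x, q, p)
    s_up <- welch_psd(up, fs, seg_s)
    s_dn <- welch_psd(dn, fs, seg_s)
    gm <- sqrt(approx(s_up$freq, s_up$psd, xout = grid, rule = 2)$y *
                 approx(s_dn$freq, s_dn$psd, xout = grid, rule = 2)$y)
    frac_h[, k] <- gm
  }
  fractal <- apply(frac_h, 1, median)
  keep <- grid >= band[1] & grid <= band[2]
  out <- tibble::tibble(freq = grid[keep],
                        psd_total = total$psd[keep],
                        psd_fractal = fractal[keep],
                        psd_oscillatory = total$psd[keep] - fractal[keep])
  attr(out, "band") <- band
  attr(out, "hset") <- hset
  attr(out, "fs") <- fs
  class(out) <- c("ppg_spectral_split", class(out))
  out
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Fractal power fraction
#'
#' Percentage of total band power attributable to the fractal PSD
#' component: `100 * integral(psd_fractal) / integral(psd_total)`
#' (trapezoidal), clipped to 0--100.
#'
#' @param split A [irasa_split()] result.
#' @return Percentage in `[0, 100]`, `NA` if the total power is zero.
#' @export
fractal_fraction <- function(split) {
  trapz <- function(y) sum(diff(split$freq) * (head(y, -1) + tail(y, -1)) / 2)
  tot <- trapz(split$psd_total)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  min(100, max(0, 100 * trapz(split$psd_fractal) / tot))
}

#' Power-law fit to the fractal PSD
#'
#' Ordinary least squares of `log10(psd_fractal)` on `log10(freq)`;
#' the spectral exponent is `beta = -slope`, and the relative uncertainty is
#' `100 * SE(slope) / |slope|` from the fit's variance--covariance matrix.
#' Non-positive PSD bins are dropped; at least 10 must remain.
#'
#' @param split A [irasa_split()] result (or any data frame with `freq` and
#'   `psd_fractal`).
#' @return An object of class `ppg_powerlaw`: a list with `beta`,
#'   `log_intercept`, `rel_uncertainty_pct`, `n_bins`, and the underlying
#'   `lm` fit.
#' @export
fit_powerlaw <- function(split) {
  ok <- is.finite(split$psd_fractal) & split$psd_fractal > 0 &
    split$freq > 0
  if (sum(ok) < 10) stop("fewer than 10 positive PSD bins; cannot fit")
  df <- data.frame(lf = log10(split$freq[ok]),
                   lp = log10(split$psd_fractal[ok]))
  fit <- lm(lp ~ lf, data = df)
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(sqrt(vcov(fit)[2, 2]))
  structure(list(beta = -slope,
                 log_intercept = unname(coef(fit)[1]),
                 rel_uncertainty_pct = 100 * se / max(abs(slope), 1e-300),
                 n_bins = sum(ok), fit = fit),
            class = "ppg_powerlaw")
}

#' @export
print.ppg_powerlaw <- function(x, ...) {
  cat(sprintf("power-law fit: beta = %.3f (rel. uncertainty %.2f%%, %d bins)\n",
              x$beta, x$rel_uncertainty_pct, x$n_bins))
  invisible(x)
}

#' @rdname fit_powerlaw
#' @param x A `ppg_powerlaw` object.
#' @param ... Unused.
#' @method tidy ppg_powerlaw
#' @export
tidy.ppg_powerlaw <- function(x, ...) {
  vc <- suppressWarnings(vcov(x$fit))
  tibble::tibble(term = c("log_intercept", "beta"),
                 estimate = c(x$log_intercept, x$beta),
                 std.error = sqrt(c(vc[1, 1], vc[2, 2])))
}

#' @rdname fit_powerlaw
#' @method glance ppg_powerlaw
#' @export
glance.ppg_powerlaw <- function(x, ...) {
  tibble::tibble(beta = x$beta, rel_uncertainty_pct = x$rel_uncertainty_pct,
                 n_bins = x$n_bins,
                 r.squared = suppressWarnings(summary(x$fit)$r.squared))
}

#' Plot an IRASA spectral split
#'
#' Log-log overlay of the total, fractal and oscillatory PSD components.
#'
#' @param object A `ppg_spectral_split`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ppg_spectral_split
#' @export
autoplot.ppg_spectral_split <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"freq",
                            names_to = "component", values_to = "psd")
  df$psd[df$psd <= 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD")
}

#' Morse-wavelet component decomposition
#'
#' Continuous wavelet filtering with a generalized Morse wavelet (symmetry
#' parameter gamma = 3, time-bandwidth product 60), evaluated by FFT. Each
#' component is the real part of the analytic wavelet transform at the
#' scale whose center (peak) frequency matches the requested frequency, so
#' it is a real band-limited time series of the same length as the input.
#'
#' @param x Numeric series (100 s at 50 Hz is the intended use; other
#'   lengths are accepted with a message).
#' @param fs Sampling rate, Hz.
#' @param center_freqs Center frequencies, Hz, descending (default: the
#'   half-octave ladder 11.63 down to 0.51 Hz).
#' @return A tibble of class `ppg_wavelet_bank` with one column per center
#'   frequency (named `w<freq>`), a `center_freqs` attribute, and
#'   `nrow(x)` rows.
#' @export
wavelet_components <- function(x, fs,
                               center_freqs = c(11.63, 8.23, 5.82, 4.11,
                                                2.91, 2.06, 1.45, 1.03,
                                                0.73, 0.51)) {
  n <- length(x)
  gamma <- 3
  beta <- 60 / gamma # time-bandwidth P^2 = beta * gamma = 60
  wpeak <- (beta / gamma)^(1 / gamma)
  keep <- center_freqs < fs / 2
  if (!all(keep)) {
    warning("dropping center frequencies at or above Nyquist: ",
            paste(center_freqs[!keep], collapse = ", "))
    center_freqs <- center_freqs[keep]
  }
  X <- fft(x - mean(x))
  w <- 2 * pi * (seq_len(n) - 1) / n # radian frequency per sample
  w[w > pi] <- 0 # keep analytic (positive-frequency) side only
  cols <- lapply(center_freqs, function(fc) {
    s <- wpeak / (2 * pi * fc / fs) # scale in samples
    sw <- s * w
    psi <- numeric(n)
    pos <- sw > 0
    # log-domain evaluation, normalized to peak value 2 (analytic wavelet)
    psi[pos] <- 2 * exp(beta * log(sw[pos] / wpeak) - (sw[pos]^gamma -
                                                         wpeak^gamma))
    Re(fft(X * psi, inverse = TRUE) / n)
  })
  names(cols) <- paste0("w", center_freqs)
  out <- tibble::as_tibble(cols)
  attr(out, "center_freqs") <- center_freqs
  attr(out, "fs") <- fs
  class(out) <- c("ppg_wavelet_bank", class(out))
  out
}
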