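#' Ornstein--Uhlenbeck parameter track
#'
#' Generates a stationary Ornstein--Uhlenbeck (OU) process around a base
#' value, used to emulate the slow drift of hemodynamic parameters
#' (peripheral resistance, central compliance, stroke volume, heart rate)
#' between cardiac cycles. The discretization is exact: over a step
#' `dt = 1/fs` the process decays by `exp(-dt/tau_s)` with the matching
#' innovation variance, so the sampled series has exactly the stationary
#' mean `base` and standard deviation `rel_sigma * base` at any `fs`.
#' Values are clipped to `[0.2, 5] * base` to keep the circuit physiological.
#'
#' @param base Base (mean) value of the parameter; must be positive.
#' @param rel_sigma Relative stationary standard deviation (0 gives a
#'   constant track).
#' @param tau_s Correlation time in seconds (> 0); the lag-`tau_s`
#'   autocorrelation of the track is `exp(-1)`.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- ou_track(1, 0.1, tau_s = 30, n = 5000, fs = 50, seed = 1)
#' sd(x) # close to 0.1
#' @export
ou_track <- function(base, rel_sigma, tau_s, n, fs, seed = NULL) {
  stopifnot(base > 0, tau_s > 0, n >= 1, fs > 0, rel_sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rel_sigma == 0) return(rep(base, n))
  sigma <- rel_sigma * base
  a <- exp(-1 / (fs * tau_s))
  innov_sd <- sigma * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  z <- rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + z[i]
  pmin(pmax(base + x, 0.2 * base), 5 * base)
}

#' Power-law (1/f^beta) noise
#'
#' Spectral synthesis of Gaussian noise whose power spectral density follows
#' `1/f^beta`, used as the additive "fractal" observation noise on the
#' simulated PPG channel. The series is standardized to unit standard
#' deviation before scaling by `amplitude`.
#'
#' @param n Number of samples.
#' @param beta Spectral exponent (0 = white noise, 1 = pink, 2 = brown).
#' @param amplitude Standard deviation of the returned series.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with mean ~0 and sd `amplitude`.
#' @export
rnoise_powerlaw <- function(n, beta, amplitude = 1, seed = NULL) {
  stopifnot(n >= 2, beta >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) # two-sided frequency index, symmetric
  scale <- ifelse(f == 0, 0, f^(-beta / 2))
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  x <- x - mean(x)
  x / sd(x) * amplitude
}

#' Fractional Brownian motion
#'
#' Exact synthesis via Davies--Harte circulant embedding of fractional
#' Gaussian noise, then cumulative summation. Used as a reference signal
#' with known Higuchi fractal dimension `2 - H`.
#'
#' @param n Number of samples of the motion.
#' @param H Hurst exponent in (0, 1).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
rfbm <- function(n, H, seed = NULL) {
  stopifnot(n >= 2, H > 0, H < 1)
  if (!is.null(seed)) set.seed(seed)
  if (abs(H - 0.5) < 1e-12) return(cumsum(rnorm(n)))
  m <- n # fGn length
  k <- 0:m
  g <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  row1 <- c(g, g[m:2]) # circulant first row, length 2m
  lam <- Re(fft(row1))
  lam[lam < 0] <- 0 # tiny negatives from round-off
  M <- 2 * m
  z <- complex(real = rnorm(M), imaginary = rnorm(M))
  fgn <- Re(fft(sqrt(lam / M) * z, inverse = TRUE))[seq_len(m)]
  cumsum(fgn)
}
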