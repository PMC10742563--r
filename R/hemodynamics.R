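#' Per-beat peripheral resistance
#'
#' `R = MAP / CO`, in mmHg.min/L when `MAP` is in mmHg and `CO` in L/min.
#' Beats with non-positive cardiac output return `NA`.
#'
#' @param MAP Mean arterial pressure, mmHg (vectorized).
#' @param CO Cardiac output, L/min.
#' @return Numeric vector of resistances.
#' @export
estimate_R <- function(MAP, CO) {
  ifelse(is.finite(CO) & CO > 0, MAP / CO, NA_real_)
}

#' Per-beat central compliance surrogate
#'
#' `C1 = AC / PP`: the ratio of the pulsatile PPG amplitude (a.u.) to the
#' pulse pressure (mmHg). The scale is arbitrary (optical units per mmHg);
#' only within-subject trends are meaningful.
#'
#' @param AC Pulsatile PPG amplitude, a.u.
#' @param PP Pulse pressure, mmHg.
#' @return Numeric vector; `NA` where `PP <= 0`.
#' @export
estimate_C1 <- function(AC, PP) {
  ifelse(is.finite(PP) & PP > 0, AC / PP, NA_real_)
}

#' Reconstruct a one-beat inflow waveform from cardiac output
#'
#' Half-sine ejection whose integral equals the per-beat stroke volume
#' implied by the mean cardiac output, `SV = CO * interval / 60 * 1000` mL.
#'
#' @param co_mean Mean cardiac output over the beat, L/min (> 0).
#' @param interval_s Beat interval, s.
#' @param fs Sampling rate, Hz.
#' @param systole_fraction Ejection fraction of the beat (default 0.35).
#' @return Numeric inflow waveform in mL/s of length
#'   `round(interval_s * fs)`.
#' @export
reconstruct_inflow <- function(co_mean, interval_s, fs,
                               systole_fraction = 0.35) {
  stopifnot(co_mean > 0, interval_s > 0)
  sv <- co_mean * interval_s / 60 * 1000
  make_inflow(60 / interval_s, sv, fs, 1, systole_fraction)
}

# Complex Fourier coefficients of x at harmonics k*f0 (k = 0..n_harm) by
# direct projection on the sampling grid.
harmonics_of <- function(x, fs, f0, n_harm) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  vapply(0:n_harm, function(k) {
    c0 <- sum(x * exp(-2i * pi * k * f0 * t)) / n
    if (k == 0) c0 else 2 * c0
  }, complex(1))
}

#' Fit distal compliance and inertance by harmonic Windkessel matching
#'
#' With `R` and `C1` held at their beat-level estimates, evaluates the WK4
#' transfer from inflow to peripheral pressure harmonic by harmonic (first
#' `n_harm` harmonics of the beat fundamental) and selects `(C2, L)`
#' minimizing the root-mean-square misfit `RMS = sqrt(SSE / (N - 1))`
#' between the modeled and measured pressure over the window. A log-scale
#' grid search is refined by Nelder--Mead (at most 200 iterations; if the
#' refinement does not converge the grid optimum is returned with
#' `converged = FALSE`).
#'
#' @param q_in Inflow series over the window, mL/s.
#' @param p_p Measured peripheral pressure over the same window, mmHg.
#' @param fs Sampling rate, Hz.
#' @param R,C1 Fixed resistance (mmHg.s/mL) and central compliance
#'   (mL/mmHg) in circuit units.
#' @param f0 Beat fundamental frequency, Hz.
#' @param n_harm Number of harmonics (default 10).
#' @param grid_n Grid points per axis for the coarse search (default 15).
#' @return A tibble of class `wk4_fit`: `C2`, `L`, `fit_rms`, `converged`.
#' @export
fit_C2_L <- function(q_in, p_p, fs, R, C1, f0, n_harm = 10, grid_n = 15) {
  stopifnot(length(q_in) == length(p_p), f0 > 0, R > 0, C1 > 0)
  n <- length(p_p)
  t <- (seq_len(n) - 1) / fs
  Q <- harmonics_of(q_in, fs, f0, n_harm)
  E <- exp(2i * pi * outer(t, (0:n_harm) * f0)) # n x (n_harm+1)
  rms_of <- function(C2, L) {
    H <- wk4_transfer((0:n_harm) * f0, R, C1, C2, L)
    model <- Re(E %*% (H * Q))
    sqrt(sum((model - p_p)^2) / (n - 1))
  }
  C2_grid <- exp(seq(log(0.01 * C1), log(10 * C1), length.out = grid_n))
  L_grid <- exp(seq(log(1e-4), log(1), length.out = grid_n))
  rms_grid <- outer(C2_grid, L_grid, Vectorize(rms_of))
  k <- arrayInd(which.min(rms_grid), dim(rms_grid))
  best <- c(C2_grid[k[1]], L_grid[k[2]])
  opt <- optim(log(best), function(p) rms_of(exp(p[1]), exp(p[2])),
               method = "Nelder-Mead", control = list(maxit = 200))
  converged <- opt$convergence == 0
  if (converged && opt$value <= rms_grid[k]) {
    C2 <- exp(opt$par[1]); L <- exp(opt$par[2]); rms <- opt$value
  } else {
    C2 <- best[1]; L <- best[2]; rms <- rms_grid[k]
    converged <- FALSE
  }
  out <- tibble::tibble(C2 = C2, L = L, fit_rms = rms,
                        converged = converged)
  class(out) <- c("wk4_fit", class(out))
  out
}

#' Per-beat hemodynamic track
#'
#' Combines the simple per-beat estimators: `R = MAP/CO` (mmHg.min/L) and
#' `C1 = AC/PP` (a.u./mmHg), returned alongside the beat table columns
#' needed downstream.
#'
#' @param beats Flagged beat table (needs `MAP`, `co_mean`, `AC`, `PP`).
#' @param valid_only Drop invalid beats (default TRUE).
#' @return A tibble with `beat`, `t_s` (foot time), `R`, `C1`, plus
#'   passthrough hemodynamic columns.
#' @export
hemo_track <- function(beats, valid_only = TRUE) {
  fs <- attr(beats, "fs")
  df <- if (valid_only && "valid" %in% names(beats))
    dplyr::filter(beats, .data$valid) else beats
  tibble::tibble(
    beat = df$beat,
    t_s = (df$foot_idx - 1) / fs,
    R = if (all(c("MAP", "co_mean") %in% names(df)))
      estimate_R(df$MAP, df$co_mean) else NA_real_,
    C1 = if (all(c("AC", "PP") %in% names(df)))
      estimate_C1(df$AC, df$PP) else NA_real_,
    SBP = if ("SBP" %in% names(df)) df$SBP else NA_real_,
    DBP = if ("DBP" %in% names(df)) df$DBP else NA_real_,
    MAP = if ("MAP" %in% names(df)) df$MAP else NA_real_,
    PP = if ("PP" %in% names(df)) df$PP else NA_real_,
    co = if ("co_mean" %in% names(df)) df$co_mean else NA_real_
  )
}

#' Windowed fluctuation (standard deviation) of hemodynamic tracks
#'
#' The fluctuation measure sigma: the sample standard deviation of each
#' per-beat parameter within each analysis window. Windows with fewer than
#' two contributing beats yield `NA`.
#'
#' @param track Output of [hemo_track()] (has `t_s` plus value columns).
#' @param windows A [make_windows()] table.
#' @param cols Columns of `track` to summarize (default all numeric value
#'   columns).
#' @return A tibble: `window`, then `sigma_<col>` and `mean_<col>` for each
#'   requested column.
#' @export
windowed_sigma <- function(track, windows,
                           cols = setdiff(names(track), c("beat", "t_s"))) {
  rows <- lapply(seq_len(nrow(windows)), function(k) {
    sel <- track$t_s >= windows$start_s[k] & track$t_s < windows$end_s[k]
    vals <- track[sel, cols, drop = FALSE]
    out <- list(window = windows$window[k])
    for (cl in cols) {
      v <- vals[[cl]][is.finite(vals[[cl]])]
      out[[paste0("sigma_", cl)]] <- if (length(v) >= 2) sd(v) else NA_real_
      out[[paste0("mean_", cl)]] <- if (length(v) >= 1) mean(v) else NA_real_
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows)
}
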