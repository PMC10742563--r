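#' Simulation configuration for the four-element Windkessel model
#'
#' Bundles every knob of the synthetic PPG/ABP/CO generator. The circuit is
#' the classical WK4 lumped model: an inflow source `q_in` (the heart)
#' drives a central compliance `C1`, an inertance `L` feeding a distal
#' compliance `C2`, which drains through the peripheral resistance `R`.
#' Slow physiological drift is emulated by Ornstein--Uhlenbeck modulation of
#' selected parameters; the optical (PPG) channel adds 1/f^beta "fractal"
#' noise and white measurement noise.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz (default 50).
#' @param hr_bpm Heart rate in beats per minute.
#' @param sv_ml Stroke volume per beat in mL.
#' @param R0 Peripheral resistance, mmHg.s/mL.
#' @param C1_0 Central compliance, mL/mmHg.
#' @param C2_0 Distal compliance, mL/mmHg.
#' @param L0 Inertance, mmHg.s^2/mL.
#' @param systole_fraction Fraction of each beat spent ejecting (half-sine).
#' @param fluct Named list of OU modulations, names among
#'   `c("R", "C1", "sv", "hr")`, each `c(rel_sigma, tau_s)`: relative
#'   stationary sd (0--0.5) and correlation time in seconds.
#' @param frac_noise Length-2 numeric `c(amplitude, beta)`: sd and spectral
#'   exponent (0--2) of additive power-law noise on the ppg channel. The
#'   amplitude is in ppg units, or relative to the sd of the clean
#'   pulsatile ppg when `frac_noise_relative` is set.
#' @param frac_noise_relative Interpret the noise amplitude as a fraction
#'   of the clean ppg standard deviation (default FALSE).
#' @param meas_noise_sd White observation noise sd on the ppg channel.
#' @param ppg_gain,ppg_offset Affine map from peripheral pressure to the
#'   ppg channel (a.u.).
#' @param couple_noise_gain If nonzero, the power-law noise amplitude is
#'   modulated by the (lagged, smoothed) mean arterial pressure:
#'   `amp * clip(1 + gain * (MAP_lag - mean)/sd(MAP), 0.3, 2)`. This
#'   installs a hemodynamics-to-complexity causal pathway by construction
#'   while keeping the modulation bounded.
#' @param couple_lag_s Lag (s) of the MAP-driven noise modulation.
#' @param transient_s Initial span flagged as transient (discarded by
#'   downstream analyses); default 10 s.
#' @param seed Integer seed; the whole record is reproducible given the seed.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(duration_s, fs = 50, hr_bpm = 75, sv_ml = 66,
                       R0 = 1.0, C1_0 = 1.5, C2_0 = 0.1, L0 = 0.02,
                       systole_fraction = 0.35,
                       fluct = list(),
                       frac_noise = c(0, 1), frac_noise_relative = FALSE,
                       meas_noise_sd = 0,
                       ppg_gain = 0.02, ppg_offset = 1,
                       couple_noise_gain = 0, couple_lag_s = 10,
                       transient_s = 10, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, fs * duration_s >= 2,
            hr_bpm >= 30, hr_bpm <= 200, sv_ml > 0,
            R0 > 0, C1_0 > 0, C2_0 > 0, L0 > 0,
            systole_fraction > 0, systole_fraction < 1,
            length(frac_noise) == 2, frac_noise[1] >= 0,
            frac_noise[2] >= 0, frac_noise[2] <= 2)
  ok <- c("R", "C1", "sv", "hr")
  if (length(fluct)) {
    stopifnot(all(names(fluct) %in% ok))
    for (f in fluct) stopifnot(length(f) == 2, f[1] >= 0, f[1] <= 0.5, f[2] > 0)
  }
  structure(list(
    duration_s = duration_s, fs = fs, hr_bpm = hr_bpm, sv_ml = sv_ml,
    R0 = R0, C1_0 = C1_0, C2_0 = C2_0, L0 = L0,
    systole_fraction = systole_fraction, fluct = fluct,
    frac_noise = frac_noise, frac_noise_relative = isTRUE(frac_noise_relative),
    meas_noise_sd = meas_noise_sd,
    ppg_gain = ppg_gain, ppg_offset = ppg_offset,
    couple_noise_gain = couple_noise_gain, couple_lag_s = couple_lag_s,
    transient_s = transient_s, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Half-sine systolic inflow waveform
#'
#' Builds the inflow (current-source) drive of the Windkessel model: a
#' half-sine ejection during systole and zero flow in diastole, with each
#' beat's integral equal to the stroke volume.
#'
#' @param hr_bpm Heart rate, beats per minute (30--200).
#' @param sv_ml Stroke volume, mL (> 0).
#' @param fs Sampling rate, Hz.
#' @param n_beats Number of beats.
#' @param systole_fraction Fraction of the beat spent ejecting.
#' @return Numeric vector of inflow in mL/s, length
#'   `round(n_beats * 60 / hr_bpm * fs)`.
#' @examples
#' q <- make_inflow(60, 70, fs = 50, n_beats = 1)
#' sum(q) / 50 # ~70 mL
#' @export
make_inflow <- function(hr_bpm, sv_ml, fs, n_beats,
                        systole_fraction = 0.35) {
  if (!is.finite(sv_ml) || sv_ml <= 0) stop("sv_ml must be positive")
  if (!is.finite(hr_bpm) || hr_bpm < 30 || hr_bpm > 200)
    stop("hr_bpm must be in [30, 200]")
  stopifnot(systole_fraction > 0, systole_fraction < 1)
  interval <- 60 / hr_bpm
  n <- round(n_beats * interval * fs)
  t <- (seq_len(n) - 1) / fs
  inflow_at(t, onsets = (seq_len(n_beats) - 1) * interval,
            intervals = rep(interval, n_beats),
            sv = rep(sv_ml, n_beats), systole_fraction)
}

# Evaluate the beat-train inflow at arbitrary times. Each beat ejects a
# half-sine over the first systole_fraction of its interval with unit-exact
# area sv (continuous-time; the sampled Riemann sum is within O(1/fs^2)).
inflow_at <- function(t, onsets, intervals, sv, systole_fraction) {
  b <- findInterval(t, onsets)
  q <- numeric(length(t))
  in_beat <- b >= 1
  ph <- t[in_beat] - onsets[b[in_beat]]
  ts <- intervals[b[in_beat]] * systole_fraction
  amp <- sv[b[in_beat]] * pi / (2 * ts)
  qq <- ifelse(ph < ts, amp * sin(pi * ph / ts), 0)
  q[in_beat] <- qq
  q
}

#' WK4 frequency response from inflow to peripheral pressure
#'
#' Transfer function `H(f) = p_p / q_in` of the four-element Windkessel
#' circuit, `H = 1 / ((i w C2 + 1/R) (1 - w^2 C1 L) + i w C1)` with
#' `w = 2 pi f`; at `f = 0` it reduces to `R`.
#'
#' @param f Frequency in Hz (vector).
#' @param R,C1,C2,L Circuit parameters (consistent units).
#' @return Complex vector of the same length as `f` (mmHg per mL/s).
#' @export
wk4_transfer <- function(f, R, C1, C2, L) {
  w <- 2 * pi * f
  iw <- complex(imaginary = w)
  H <- 1 / ((iw * C2 + 1 / R) * (1 - w^2 * C1 * L) + iw * C1)
  H[f == 0] <- R
  H
}

#' Simulate a multichannel vital-sign record with the WK4 model
#'
#' Integrates the Windkessel ODEs
#' `dq/dt = (p_c - p_p)/L`, `dp_c/dt = (q_in - q)/C1(t)`,
#' `dp_p/dt = (q - p_p/R(t))/C2`
#' on a fixed output grid at `fs`, with seeded OU drift of the selected
#' parameters, and derives the observed channels: `abp = p_p`, a surrogate
#' optical `ppg`, and an instantaneous cardiac-output track `co` (L/min).
#'
#' The ppg channel is an affine map of peripheral pressure whose gain is
#' modulated by the instantaneous compliance ratio `C1(t)/C1_0` --- PPG
#' amplitude is treated as proportional to vascular distension, so the
#' beat-level ratio AC/PP tracks the true compliance --- plus power-law
#' and white observation noise.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `wk4_record` with columns `t`, `q_in`, `q`,
#'   `p_c`, `p_p`, `ppg`, `abp`, `co`, and attributes `fs`, `config`,
#'   `transient_s`, and `truth` (a per-beat tibble of ground-truth
#'   parameter tracks: `onset_s`, `interval_s`, `hr`, `sv`, `co`, `R`,
#'   `C1`).
#' @export
simulate_wk4 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  fs <- cf$fs
  n <- round(cf$duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  fl <- function(name) {
    if (!is.null(cf$fluct[[name]])) cf$fluct[[name]] else c(0, 1)
  }
  # slow parameter tracks on the output grid (seeded sub-streams)
  seeds <- sample.int(.Machine$integer.max - 1, 6)
  R_t <- ou_track(cf$R0, fl("R")[1], fl("R")[2], n, fs, seed = seeds[1])
  C1_t <- ou_track(cf$C1_0, fl("C1")[1], fl("C1")[2], n, fs, seed = seeds[2])
  hr_t <- ou_track(cf$hr_bpm, fl("hr")[1], fl("hr")[2], n, fs, seed = seeds[3])
  sv_t <- ou_track(cf$sv_ml, fl("sv")[1], fl("sv")[2], n, fs, seed = seeds[4])

  # beat sequence: each beat reads hr/sv at its onset
  onsets <- c(); intervals <- c(); svs <- c(); hrs <- c()
  t0 <- 0
  while (t0 < cf$duration_s) {
    i <- min(n, floor(t0 * fs) + 1)
    hr_b <- min(200, max(30, hr_t[i]))
    iv <- 60 / hr_b
    onsets <- c(onsets, t0); intervals <- c(intervals, iv)
    svs <- c(svs, sv_t[i]); hrs <- c(hrs, hr_b)
    t0 <- t0 + iv
  }
  nb <- length(onsets)

  # forcing on a 4x-oversampled grid so the adaptive integrator sees a
  # smooth, cheap interpolant
  tf <- seq(0, cf$duration_s, by = 1 / (4 * fs))
  qin_fun <- approxfun(tf, inflow_at(tf, onsets, intervals, svs,
                                     cf$systole_fraction), rule = 2)
  R_fun <- approxfun(t, R_t, rule = 2)
  C1_fun <- approxfun(t, C1_t, rule = 2)

  p_init <- cf$R0 * cf$hr_bpm * cf$sv_ml / 60 # mmHg, DC balance estimate
  rhs <- function(tt, y, parms) {
    q <- y[1]; p_c <- y[2]; p_p <- y[3]
    list(c((p_c - p_p) / cf$L0,
           (qin_fun(tt) - q) / C1_fun(tt),
           (q - p_p / R_fun(tt)) / cf$C2_0))
  }
  sol <- deSolve::ode(y = c(q = 0, p_c = p_init, p_p = p_init),
                      times = t, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-6, atol = 1e-6)
  if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol[, -1])) ||
      max(abs(sol[, c("p_c", "p_p")])) > 1e4) {
    stop("WK4 integration blew up (|p| > 1e4 mmHg) for parameter set: ",
         sprintf("R0=%g C1_0=%g C2_0=%g L0=%g hr=%g sv=%g",
                 cf$R0, cf$C1_0, cf$C2_0, cf$L0, cf$hr_bpm, cf$sv_ml))
  }
  q <- sol[, "q"]; p_c <- sol[, "p_c"]; p_p <- sol[, "p_p"]
  q_in <- inflow_at(t, onsets, intervals, svs, cf$systole_fraction)

  # instantaneous CO track (per-beat step function, L/min)
  beat_co <- svs / intervals * 60 / 1000
  beat_idx <- findInterval(t, onsets)
  beat_idx[beat_idx < 1] <- 1
  co <- beat_co[beat_idx]

  # ppg: compliance-modulated affine map of p_p + fractal + white noise
  p_ref <- mean(p_p)
  ppg_clean <- cf$ppg_gain * (C1_t / cf$C1_0) * (p_p - p_ref) + cf$ppg_offset
  amp0 <- if (cf$frac_noise_relative) cf$frac_noise[1] * sd(ppg_clean)
  else cf$frac_noise[1]
  amp <- rep(amp0, n)
  if (cf$couple_noise_gain != 0 && cf$frac_noise[1] > 0) {
    w <- max(1L, round(10 * fs)) # 10 s moving-average MAP
    map_s <- stats::filter(p_p, rep(1 / w, w), sides = 1)
    map_s[is.na(map_s)] <- p_p[is.na(map_s)]
    lag_n <- round(cf$couple_lag_s * fs)
    map_lag <- c(rep(map_s[1], lag_n), head(map_s, n - lag_n))
    z <- (map_lag - mean(map_lag)) / max(sd(map_lag), 1e-12)
    amp <- amp0 * pmin(2, pmax(0.3, 1 + cf$couple_noise_gain * z))
  }
  noise <- if (cf$frac_noise[1] > 0)
    amp * rnoise_powerlaw(n, cf$frac_noise[2], 1) else numeric(n)
  wn <- if (cf$meas_noise_sd > 0) rnorm(n, 0, cf$meas_noise_sd) else numeric(n)
  ppg <- ppg_clean + noise + wn

  truth <- tibble::tibble(
    onset_s = onsets, interval_s = intervals, hr = hrs, sv = svs,
    co = beat_co,
    R = vapply(seq_len(nb), function(b) {
      i0 <- floor(onsets[b] * fs) + 1
      i1 <- min(n, floor((onsets[b] + intervals[b]) * fs))
      mean(R_t[i0:i1])
    }, numeric(1)),
    C1 = vapply(seq_len(nb), function(b) {
      i0 <- floor(onsets[b] * fs) + 1
      i1 <- min(n, floor((onsets[b] + intervals[b]) * fs))
      mean(C1_t[i0:i1])
    }, numeric(1))
  )

  out <- tibble::tibble(t = t, q_in = q_in, q = q, p_c = p_c, p_p = p_p,
                        ppg = ppg, abp = p_p, co = co)
  attr(out, "fs") <- fs
  attr(out, "config") <- cf
  attr(out, "transient_s") <- cf$transient_s
  attr(out, "truth") <- truth
  class(out) <- c("wk4_record", class(out))
  out
}

#' @export
print.wk4_record <- function(x, ...) {
  cf <- attr(x, "config")
  cat(sprintf("<wk4_record> %.0f s at %g Hz, HR %g bpm, %d beats\n",
              cf$duration_s, cf$fs, cf$hr_bpm, nrow(attr(x, "truth"))))
  NextMethod()
}

#' Plot a simulated WK4 record
#'
#' Faceted channel traces (pressures, inflow, ppg, co) over an optional
#' time range.
#'
#' @param object A `wk4_record`.
#' @param tlim Optional length-2 numeric time range in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wk4_record
#' @export
autoplot.wk4_record <- function(object, tlim = NULL, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "t", "p_p", "p_c", "q_in",
                  "ppg", "co"),
    -"t", names_to = "channel", values_to = "value")
  if (!is.null(tlim)) df <- dplyr::filter(df, .data$t >= tlim[1],
                                          .data$t <= tlim[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = NULL)
}
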