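---
title: "Quantifying the chaotic component of PPG and its hemodynamic associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the chaotic component of PPG and its hemodynamic associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgchaos)
```

## The problem

Photoplethysmography (PPG) is the optical pulse signal used by virtually
every wearable device. Besides the obvious cardiac oscillation, PPG carries
an aperiodic, power-law ("fractal" or "chaotic") component whose strength
appears to track the stability of the circulation: the less stationary the
hemodynamics — cardiac output (CO), blood pressure, vascular compliance —
the more fractal power the optical signal carries, and the more informative
complexity measures become for estimating pressure. `ppgchaos` implements a
complete, testable pipeline for studying that relationship:

1. a four-element Windkessel (WK4) simulator that generates multichannel
   records (PPG, arterial pressure, CO) with controllable "physiological"
   drift and fractal observation noise — the package's synthetic test bed;
2. beat detection, detrending and per-cardiac-cycle quality rules;
3. per-beat hemodynamic estimation (peripheral resistance `R`, compliance
   surrogate `C1`, and a harmonic-domain fit of distal compliance `C2` and
   inertance `L`);
4. IRASA separation of the PSD into fractal and oscillatory parts, with a
   power-law fit and its uncertainty;
5. fractal dimensions (Higuchi, Katz), entropies (sample, approximate,
   fuzzy, recurrence ENTR), false-nearest-neighbour embedding dimension
   and HRV LF/HF, over three sampling schemes;
6. window-level association analyses: intrasubject Pearson correlation,
   sensitivity slopes under fluctuation splits, and bivariate
   Granger-causality classification.

Everything runs end-to-end on synthetic records; no data download is
needed.

## The hemodynamic model

The WK4 circuit treats the heart as a flow source $q_{in}(t)$ (half-sine
ejection during systole, integral = stroke volume), feeding a central
compliance $C_1$, an inertance $L$, a distal compliance $C_2$ and a
peripheral resistance $R$:

$$
\frac{dq}{dt} = \frac{p_c - p_p}{L},\qquad
\frac{dp_c}{dt} = \frac{q_{in} - q}{C_1(t)},\qquad
\frac{dp_p}{dt} = \frac{1}{C_2}\Big(q - \frac{p_p}{R}\Big).
$$

`simulate_wk4()` integrates these equations with `deSolve::lsoda`
(relative tolerance $10^{-6}$) on a fixed 50 Hz output grid, with the
forcing evaluated on a 4x-oversampled interpolant. At DC the circuit obeys
$\bar p_p = R\,\bar q_{in}$, which the tests verify to 2%.

Slow physiological drift is modelled as exact-discretization
Ornstein--Uhlenbeck (OU) processes on $R$, $C_1$, stroke volume and heart
rate. An OU process was chosen because it is stationary, has a single
interpretable fluctuation magnitude $\sigma$ (the same standard-deviation
notion used as the fluctuation measure downstream) and a single timescale,
and is exactly seedable. Tracks are clipped to $[0.2, 5]\times$ base to
keep the circuit in a physiological regime.

**The PPG surrogate.** PPG amplitude reflects vascular distension, i.e.
locally $\Delta V \approx C_1 \Delta p$. The ppg channel is therefore an
affine map of peripheral pressure whose *gain* is modulated by the
instantaneous compliance ratio $C_1(t)/C_1(0)$: within a beat the waveform
shape is an affine copy of pressure (so the beat-level PPG/BP correlation
is near 1 for clean signal), while across beats the ratio AC/PP tracks the
true compliance — which is exactly what the downstream estimator
`estimate_C1()` assumes. A gain-constant affine map would make AC/PP
constant and the compliance track unrecoverable. On top of the clean
signal the generator adds $1/f^\beta$ observation noise (spectral
synthesis, unit-sd standardized) and white measurement noise.

**Causal coupling.** For causality experiments the generator can modulate
the fractal-noise amplitude by the subject's lagged, 10-s-smoothed mean
arterial pressure (`couple_noise_gain`, default lag 10 s), with the
modulation factor clipped to $[0.3, 2]$. This installs, by construction, a
hemodynamics $\to$ complexity pathway that the Granger stage should
detect. Unbounded modulation was rejected: occasional large noise
excursions corrupt beat detection and window quality, which is realistic
but destroys the controlled contrast the synthetic study needs.

## Preprocessing

`detect_feet()` uses a slope-sum transform (0.13 s window of positive
slopes) with a blockwise adaptive threshold (half the 95th percentile per
10 s block) and a 0.3 s refractory period; the foot is the last sample
attaining the local minimum in the search span before each crossing, so a
flat diastolic baseline resolves to the upstroke onset. On simulated
records the feet land within one sample of constructed pulse onsets and
within 40 ms of the observable pressure minimum; note that the peripheral
foot physically lags the inflow onset by roughly $\sqrt{LC_2}$ (tens of
milliseconds), which is a property of the circuit, not of the detector.

The baseline (DC) is the piecewise-linear interpolation through the feet;
the pulsatile residual (AC) is zero at every foot by construction. Four
per-beat quality rules are applied in a fixed order (first hit names the
reject reason): pulse pressure below 15 mmHg; PPG--BP waveform correlation
below 0.8 (both waveforms resampled to 50 points so equal-length series
are compared); beat interval outside 0.5--1.5 s; and negative raw-PPG
skewness of any analysis window containing the beat (Fisher--Pearson
$g_1$). Analysis windows are 100 s long with a 5 s hop — the hop
interpretation reproduces the expected one-window-per-few-seconds density
— and a window is discarded when more than 10 s of it is invalid or
uncovered. The per-beat scheme chunks valid beats into disjoint blocks of
100 cycles.

## Hemodynamic estimation

Per beat, $R = \mathrm{MAP}/\mathrm{CO}$ (mmHg·min/L) and $C_1 =
\mathrm{AC}/\mathrm{PP}$ (arbitrary optical units per mmHg — only
within-subject trends are meaningful). $C_2$ and $L$ are then fitted with
$R$ and $C_1$ held fixed (the stated two-stage order): the inflow is
decomposed into its first 10 harmonics of the beat fundamental, the WK4
frequency response maps them to modeled pressure, and
$(C_2, L)$ minimize $\mathrm{RMS} = \sqrt{\mathrm{SSE}/(N-1)}$ over the
window. A log-spaced grid ($C_2 \in [0.01, 10]\,C_1$,
$L \in [10^{-4}, 1]$) guards against the multimodality of the RMS surface
and is refined by Nelder--Mead (200 iterations; non-convergence falls back
to the grid optimum with a flag). Self-consistency on simulated records
recovers $C_2$ within 10% and $L$ within 15% with sub-0.5 mmHg residuals.
Ten harmonics follow the usual convention for Windkessel fits; the inflow
for fitting can be reconstructed from the per-beat CO
(`reconstruct_inflow()`), since only CO — not a flow waveform — is
available in practice. Fits are performed per 100 s window.

## Spectral separation (IRASA) and wavelets

`irasa_split()` resamples the signal by each factor $h$ and its reciprocal
(default $h = 1.10, 1.15, \dots, 1.90$, the original convention for the
method), computes Hann-tapered Welch spectra (10 s segments, 50% overlap —
enough to resolve the 0.5 Hz band edge inside a 100 s window), takes the
geometric mean $\sqrt{S_h S_{1/h}}$ per pair on the common grid, and the
median across $h$. Oscillatory peaks are displaced by resampling and cancel
in the median; power-law components are invariant. The oscillatory
remainder `total - fractal` is deliberately *not* clipped at zero
pointwise; clipping happens only at the band-integral stage, where the
fractal fraction is $100\int S_{frac} / \int S_{tot}$ (trapezoidal, band
0.5--10 Hz for raw 50 Hz signal). The spectral exponent $\beta$ is the
negated OLS slope of $\log_{10}$ PSD on $\log_{10} f$, with its relative
uncertainty taken from the coefficient variance--covariance matrix; the
uncertainty demonstrably shrinks with record length.

Wavelet components use a generalized Morse wavelet (symmetry 3,
time-bandwidth 60) evaluated by FFT as an analytic filter; each component
is the real part at the scale whose peak frequency matches the requested
center frequency (default half-octave ladder 11.63 Hz down to 0.51 Hz).
Correctness is defined by energy localization (a pure tone concentrates in
the matching component), not by coefficient identity with any particular
implementation.

On resampling: `signal::resample` (polyphase FIR) performs the
anti-aliased irregular resampling; Welch, IRASA and the wavelet filter are
implemented in the package because no installed package provides them.

## Complexity measures

All scalar kernels are vector-first functions; the heavy pairwise counts
run in C++ and are verified against independent $O(n^2)$ brute-force R
implementations to $10^{-12}$ in the tests.

* **Higuchi FD** (`hfd`, $k_{max} = 10$): slope of mean normalized curve
  length versus scale in log-log; limits verified: straight line
  $\to 1$, white noise $\to 2.00 \pm 0.05$, fractional Brownian motion
  $\to 2 - H \pm 0.1$ (fBm synthesized exactly by circulant embedding).
  The fit's relative uncertainty is returned for Fig-8-style reporting.
* **Katz FD** (`kfd`): $\log_{10} n / (\log_{10} n + \log_{10}(d/L))$ with
  waveform-only distances, making it exactly 1 for a line and
  scale-invariant.
* **Entropies** (`sampen`, `apen`, `fuzzen`, $m = 4$, Chebyshev distance,
  $r = 0.2\,\mathrm{sd}$ recomputed per window — the field convention, as
  no value is otherwise prescribed): standard definitions; the sample
  entropy no-match case is capped at $\ln B + \ln 2$ and flagged rather
  than raising, and flagged windows are excluded from association
  statistics.
* **RQA ENTR** (`rqa_entr`): Shannon entropy of diagonal-line lengths
  $\ge 2$ at a recurrence threshold of 10% of the attractor diameter
  (delay 1). Sinusoids give near-zero ENTR; noise gives more.
* **FNN** (`fnn_dimension`, Kennel ratio/absolute tests 10 and 2): the
  embedding dimension is the smallest $m$ with under 5% false neighbours.
  With the standard first-ACF-zero delay the Rössler x-series yields the
  canonical dimension 3; an embedding dimension of 4 is used as the
  default for PPG.
* **HRV LF/HF** (`lf_hf`): beat intervals (PPG foot-to-foot) cubic-splined
  to 4 Hz, Welch power integrated over 0.04--0.15 and 0.15--0.40 Hz.

Three sampling schemes are supported per window: the raw 50 Hz waveform
and wavelet components over 100 s time windows, and per-beat AC/DC series
over 100-cycle beat windows with beat index as abscissa (the uneven beat
spacing is acknowledged, not corrected).

## Association analyses

Per subject: Pearson correlation between per-window feature and
hemodynamic series with the t-distribution p-value; OLS sensitivity slopes
$\partial\,\text{feature}/\partial\,\text{target}$ across windows;
cross-subject median splits on a fluctuation measure $\sigma$ (ties to the
low group) compared by two-sided Wilcoxon rank-sum. The abstract
sensitivity functions linking morphology/FD to hemodynamics are
represented empirically by these regression slopes conditioned on
fluctuation bins — the only form in which such sensitivities are ever
observable.

Granger classification runs bivariate F-tests in both directions on
per-window series. Series failing an augmented Dickey--Fuller check
(constant, 5% critical value $-2.86$) are differenced — both of them, to
keep the pairing. The lag cap is the window-hop equivalent of a 50 s
maximum lag (10 at the 5 s hop), reduced by BIC per direction when a
shorter fit is better (the lag-selection rule under the cap is otherwise
unspecified, and BIC is the conservative choice). The two tests are *not*
multiplicity-corrected, matching the single stated $\alpha = 0.05$; the
verdict is the four-way partition (both / either one / neither
significant). Calibration on simulated VARs: planted unidirectional
coupling is recovered in $\ge 90\%$ of seeds, mutual coupling in
$\ge 80\%$, and the null non-NONE rate stays at or below 12% (two tests at
$\alpha = 0.05$).

## The synthetic study

`synth_cohort()` fixes the study conditions: 20 subjects, 900 s records at
50 Hz (161 candidate windows — headroom over the 100-window Granger
requirement when noisy windows drop), heart rate 60--90 bpm, stroke volume
55--80 mL, $R_0 \in [0.9, 1.3]$ mmHg·s/mL, $C_1 \in [1.2, 1.8]$ mL/mmHg.
Each subject receives an OU fluctuation level $\sigma$ spread over
0.02--0.12 (relative) on $R$, $C_1$ and stroke volume, and $1/f$
observation noise with amplitude $0.08 + 1.2\sigma$ relative to the clean
ppg sd — so fractal power grows with hemodynamic fluctuation *by
construction*, yielding per-window fractal fractions of roughly 5--20%,
bracketing the few-percent (unstable surgical) to ~13% (healthy) range
reported for real cohorts. Half the subjects are additionally
MAP-coupled (gain 1.5, lag 10 s) as described above. The pipeline must
then recover (a) a positive cross-subject association between fractal
fraction and $\sigma_{CO}$ and (b) a higher non-NONE Granger rate in the
coupled arm. The acceptance suite asserts exactly these two directional
properties.

What the generator does *not* emulate: motion artifacts, sensor
decoupling, baroreflex feedback loops, respiration, arrhythmias, or any
1D/3D wave propagation. Passing tests therefore demonstrate internal
consistency of the method chain under a controlled lumped-parameter world,
not clinical performance on real recordings.

## Numerical choices and degenerate inputs

* Integration: `lsoda`, tolerances $10^{-6}$; the circuit is non-stiff at
  physiological parameters. Records are fully reproducible given the seed.
* The first 10 s of every simulation are flagged transient and excluded
  downstream.
* Degenerate inputs return flagged values instead of raising: constant
  series give HFD/KFD 1, RQA 0, capped SampEn; flat signals refuse beat
  detection with a clear error.
* Problem sizes in the tests (5000-sample windows, 20-subject studies,
  100--200 seed calibrations) were chosen so every property is estimated
  with comfortable margins while the whole suite stays desk-scale.
* Indices are 1-based inside R; CSV outputs carry times in seconds.

## Known limitations

* The compliance surrogate $C_1 = \mathrm{AC}/\mathrm{PP}$ has arbitrary
  units; no absolute calibration of $C_1$, $C_2$ or $L$ is attempted.
* Granger verdicts on heavily overlapping windows (95% shared support)
  inherit the usual autocorrelation caveats; the null calibration above
  uses non-overlapping VAR draws, and the uncoupled synthetic arm shows a
  higher non-NONE rate than that idealized null. Verdicts indicate
  predictive relationships, not causation.
* The IRASA exponent for a mixture is biased toward the continuum of the
  oscillatory component when the fractal floor is weak; exponent recovery
  within $\pm 0.15$ is guaranteed only when the fractal component
  dominates the inter-harmonic continuum.
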