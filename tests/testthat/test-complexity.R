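test_that("entropies match O(n^2) brute-force counting exactly", {
  set.seed(42)
  x <- rnorm(200)
  r <- 0.3 * sd(x)
  for (m in c(2, 3)) {
    expect_equal(as.numeric(sampen(x, m, r)), bf_sampen(x, m, r),
                 tolerance = 1e-13)
    expect_equal(apen(x, m, r), bf_apen(x, m, r), tolerance = 1e-13)
    expect_equal(fuzzen(x, m, r, 2), bf_fuzzen(x, m, r, 2),
                 tolerance = 1e-13)
  }
})

test_that("recurrence entropy matches a brute-force recurrence matrix", {
  set.seed(7)
  y <- rnorm(300)
  expect_equal(as.numeric(rqa_entr(y, 4, 1, 0.1, 2)),
               bf_rqa_entr(y, 4, 1, 0.1, 2), tolerance = 1e-13)
  y2 <- as.numeric(arima.sim(list(ar = 0.9), 250))
  expect_equal(as.numeric(rqa_entr(y2, 3, 2, 0.15, 2)),
               bf_rqa_entr(y2, 3, 2, 0.15, 2), tolerance = 1e-13)
})

test_that("constant and regular series give zero entropy", {
  x <- rep(2, 100)
  expect_equal(as.numeric(sampen(x, 4, 0.1)), 0)
  expect_lt(abs(apen(x, 4, 0.1)), 1e-12)
  expect_lt(abs(fuzzen(x, 4, 0.1)), 1e-12)
  # periodic < shuffled, consistently across seeds
  wins <- sapply(1:20, function(s) {
    set.seed(s)
    p <- rep(sin(2 * pi * (1:20) / 20), 10) + rnorm(200, 0, 0.05)
    sh <- sample(p)
    r <- 0.2 * sd(p)
    as.numeric(sampen(p, 2, r)) < as.numeric(sampen(sh, 2, r))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("fuzzy entropy increases with added noise", {
  wins <- sapply(1:20, function(s) {
    set.seed(s)
    base <- sin(2 * pi * (1:300) / 30)
    lo <- base + rnorm(300, 0, 0.05)
    hi <- base + rnorm(300, 0, 0.5)
    fuzzen(lo, 4, 0.2 * sd(lo)) < fuzzen(hi, 4, 0.2 * sd(hi))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("Higuchi dimension attains its known limits", {
  expect_equal(as.numeric(hfd(1:500 * 0.3 + 2)), 1, tolerance = 1e-3)
  wn <- median(sapply(1:20, function(s) {
    set.seed(s); as.numeric(hfd(rnorm(5000)))
  }))
  expect_equal(wn, 2, tolerance = 0.05)
  for (H in c(0.3, 0.5, 0.7)) {
    v <- median(sapply(1:10, function(s)
      as.numeric(hfd(rfbm(5000, H, seed = s)))))
    expect_equal(v, 2 - H, tolerance = 0.1)
  }
  expect_equal(as.numeric(hfd(rep(1, 200))), 1) # degenerate flag path
  expect_identical(attr(hfd(rep(1, 200)), "flag"), "degenerate")
})

test_that("Katz dimension follows its closed form and invariances", {
  expect_identical(as.numeric(kfd(1:100 * 2 + 1)), 1) # line: d = Ltot
  x <- rep(c(0, 1), 50)
  n <- 99; L <- 99; d <- 1
  expect_equal(as.numeric(kfd(x)), log10(n) / (log10(n) + log10(d / L)),
               tolerance = 1e-12)
  set.seed(1)
  y <- cumsum(rnorm(200))
  expect_equal(as.numeric(kfd(3.7 * y)), as.numeric(kfd(y)),
               tolerance = 1e-12)
  expect_identical(as.numeric(kfd(rep(5, 10))), 1)
})

test_that("complexity measures honour their affine invariances", {
  set.seed(11)
  x <- as.numeric(arima.sim(list(ar = 0.8), 600))
  a <- 2.5; b <- -3
  expect_equal(as.numeric(hfd(a * x + b)), as.numeric(hfd(x)),
               tolerance = 1e-10)
  expect_equal(as.numeric(kfd(a * x + b)), as.numeric(kfd(x)),
               tolerance = 1e-10)
  # entropies with r scaled to sd are scale-invariant
  expect_equal(as.numeric(sampen(a * x + b, 3, 0.2 * sd(a * x))),
               as.numeric(sampen(x, 3, 0.2 * sd(x))), tolerance = 1e-12)
  expect_equal(fuzzen(a * x + b, 3, 0.2 * sd(a * x)),
               fuzzen(x, 3, 0.2 * sd(x)), tolerance = 1e-12)
})

test_that("sinusoids give low and noise high recurrence entropy", {
  s <- sin(2 * pi * (0:499) / 25)
  expect_lte(as.numeric(rqa_entr(s)), 0.5)
  wins <- sapply(1:20, function(sd_) {
    set.seed(sd_)
    as.numeric(rqa_entr(rnorm(500))) > as.numeric(rqa_entr(s))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("FNN finds the canonical embedding dimensions", {
  rx <- roessler_x(5000)
  tau <- embedding_delay(rx, 100)
  d <- fnn_dimension(rx, tau = tau)
  expect_equal(as.integer(d), 3L)
  set.seed(5)
  dn <- fnn_dimension(rnorm(600), max_m = 6)
  expect_identical(attr(dn, "flag"), "never_below")
})

test_that("LF/HF separates low- and high-frequency interval modulation", {
  tt <- cumsum(rep(1, 120))
  expect_gt(lf_hf(1 + 0.05 * sin(2 * pi * 0.1 * tt), tt), 5)
  expect_lt(lf_hf(1 + 0.05 * sin(2 * pi * 0.25 * tt), tt), 0.2)
  both <- 1 + 0.05 * sin(2 * pi * 0.1 * tt) + 0.05 * sin(2 * pi * 0.25 * tt)
  expect_gt(lf_hf(both, tt), 0.5)
  expect_lt(lf_hf(both, tt), 2)
})

test_that("windowed complexity is deterministic and flags degenerate input", {
  rec <- fx_c1drift()
  fs <- 50
  feet <- detect_feet(rec$ppg, fs)
  beats <- flag_outlier_beats(beat_features(rec, feet, fs), rec$ppg, fs)
  w <- make_windows(beats, nrow(rec) / fs, "time", fs)
  cx1 <- complexity_over_windows(rec, w, "raw", beats = beats, fs = fs,
                                 measures = c("hfd", "kfd", "sampen"))
  cx2 <- complexity_over_windows(rec, w, "raw", beats = beats, fs = fs,
                                 measures = c("hfd", "kfd", "sampen"))
  expect_identical(cx1, cx2)
  expect_true(all(cx1$hfd >= 1 - 1e-6))
  # constant record -> all windows degenerate
  const <- tibble::tibble(ppg = rep(1, 6000))
  wc <- tibble::tibble(window = 1L, start_s = 0, end_s = 100,
                       first_beat = NA, last_beat = NA, n_valid = 0L,
                       corrupt_s = 0, usable = TRUE)
  cxc <- complexity_over_windows(const, wc, "raw", fs = 50,
                                 measures = c("hfd", "sampen"))
  expect_true(all(cxc$degenerate))
})

test_that("per-beat and wavelet schemes produce one row per unit", {
  rec <- fx_c1drift()
  fs <- 50
  feet <- detect_feet(rec$ppg, fs)
  beats <- flag_outlier_beats(beat_features(rec, feet, fs), rec$ppg, fs)
  wb <- make_windows(beats, nrow(rec) / fs, "beats", fs)
  cx <- complexity_over_windows(rec, wb, "ac", beats = beats, fs = fs,
                                measures = c("hfd", "kfd"))
  expect_equal(nrow(cx), nrow(wb))
  wt <- make_windows(beats, nrow(rec) / fs, "time", fs)
  wt2 <- wt[wt$window <= 2, ]
  cxw <- complexity_over_windows(rec, wt2, "wavelet", fs = fs,
                                 measures = "hfd",
                                 wavelet_freqs = c(4.11, 1.45))
  expect_equal(nrow(cxw), 2 * 2)
  expect_true(all(c("wavelet_freq") %in% names(cxw)))
})
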