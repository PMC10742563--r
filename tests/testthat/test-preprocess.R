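test_that("foot detection finds pulse onsets on a constructed pulse train", {
  fs <- 50
  n <- 30 * fs
  x <- numeric(n)
  onsets <- seq(1, n - 0.3 * fs - 1, by = fs) # 1 Hz, 30 pulses
  for (o in onsets) {
    k <- 0:(0.3 * fs)
    x[o + k] <- sin(pi * k / (0.3 * fs))
  }
  feet <- detect_feet(x, fs)
  expect_equal(length(feet), 30, tolerance = 0) # one per pulse
  matched <- sapply(feet, function(f) min(abs(onsets - f)))
  expect_true(all(matched <= 1))
})

test_that("foot detection is accurate on simulated pressure waveforms", {
  rec <- fx_steady()
  fs <- 50
  feet <- detect_feet(rec$ppg, fs)
  truth <- attr(rec, "truth")
  # one foot per cardiac cycle
  expect_equal(length(feet), nrow(truth), tolerance = 1)
  # the observable foot is the per-beat pressure minimum; the detector must
  # land within 40 ms of it (inflow onset itself leads the peripheral foot
  # by the inflow-to-periphery propagation delay)
  foot_t <- (feet - 1) / fs
  steady <- foot_t > 12 & foot_t < 58
  true_feet <- sapply(which(steady), function(k) {
    b <- which.min(abs(truth$onset_s - foot_t[k]))
    i0 <- max(1, floor((truth$onset_s[b] - 0.3) * fs))
    i1 <- min(nrow(rec), ceiling((truth$onset_s[b] + 0.3) * fs))
    (i0 + which.min(rec$p_p[i0:i1]) - 2) / fs
  })
  expect_lt(max(abs(foot_t[steady] - true_feet)), 0.04)
  # and it tracks the inflow onset up to that (sub-100 ms) delay
  onset_err <- sapply(foot_t[steady], function(f)
    min(abs(attr(rec, "truth")$onset_s - f)))
  expect_lt(max(onset_err), 0.1)
})

test_that("flat signals raise a no-beats error", {
  expect_error(detect_feet(rep(1, 500), 50), "flat|no beats")
})

test_that("detrending is exact at feet and removes linear baselines", {
  set.seed(1)
  x <- cumsum(rnorm(500))
  feet <- c(10, 100, 230, 380, 480)
  d <- detrend_ppg(x, feet)
  expect_true(all(abs(d$pulsatile[feet]) < 1e-12))
  # straight line between feet -> pulsatile identically zero
  y <- 0.5 * (1:500) + 3
  d2 <- detrend_ppg(y, feet)
  expect_true(all(abs(d2$pulsatile[10:480]) < 1e-9))
  # sawtooth with feet at troughs: per-beat AC = amplitude
  fs <- 50
  saw <- rep(c(seq(0, 1, length.out = 25), seq(1, 0, length.out = 25)[-1]),
             10)
  fsaw <- which(saw == 0)
  fsaw <- fsaw[c(TRUE, diff(fsaw) > 1)] # one foot per trough
  d3 <- detrend_ppg(saw, fsaw)
  b <- beat_features(tibble::tibble(ppg = saw), fsaw, fs, d3)
  expect_equal(b$AC, rep(1, nrow(b)), tolerance = 1e-9)
})

test_that("re-detection on the pulsatile output reproduces the feet", {
  rec <- fx_steady()
  feet <- detect_feet(rec$ppg, 50)
  d <- detrend_ppg(rec$ppg, feet)
  p <- d$pulsatile
  p[is.na(p)] <- 0
  feet2 <- detect_feet(p, 50)
  common <- feet2[feet2 >= min(feet) & feet2 <= max(feet)]
  err <- sapply(common, function(f) min(abs(feet - f)))
  expect_true(all(err <= 1))
})

test_that("beat features follow their definitions", {
  fs <- 50
  rec <- fx_steady()
  feet <- detect_feet(rec$ppg, fs)
  beats <- beat_features(rec, feet, fs)
  # MAP is the time-average of pressure over the beat span
  b <- 20
  span <- feet[b]:(feet[b + 1] - 1)
  expect_equal(beats$MAP[b], mean(rec$abp[span]), tolerance = 1e-12)
  expect_equal(beats$PP[b], beats$SBP[b] - beats$DBP[b])
  # abp affine in ppg -> waveform correlation 1
  rec2 <- tibble::tibble(ppg = rec$ppg, abp = 3 * rec$ppg + 5)
  beats2 <- beat_features(rec2, feet, fs)
  expect_true(all(beats2$ppg_bp_corr > 1 - 1e-6))
})

test_that("outlier rules flag planted violations with the right reasons", {
  flagged <- flag_outlier_beats(toy_beats())
  expect_equal(sum(flagged$valid), 7)
  expect_equal(as.character(flagged$reject_reason[3]), "PP_LOW")
  expect_equal(as.character(flagged$reject_reason[6]), "INTERVAL")
  expect_equal(as.character(flagged$reject_reason[8]), "CORR_LOW")
  expect_true(all(flagged$reject_reason[flagged$valid] == "NONE"))
  # counts by reason sum to total rejects, exactly one reason per reject
  tab <- table(flagged$reject_reason[!flagged$valid])
  expect_equal(sum(tab), sum(!flagged$valid))

  clean <- toy_beats()
  clean$PP[3] <- 40; clean$interval_s[6] <- 1; clean$ppg_bp_corr[8] <- 0.99
  expect_equal(sum(flag_outlier_beats(clean)$valid), 10)
})

test_that("negative window skewness flags all beats in the window", {
  fs <- 50
  n <- 120 * fs
  set.seed(2)
  # negatively skewed signal: reflected exponential pulses
  x <- -rexp(n) + 0.01 * sin(2 * pi * (1:n) / fs)
  beats <- toy_beats()
  beats$foot_idx <- seq(1, by = 50, length.out = 10)
  beats$next_foot_idx <- beats$foot_idx + 50
  beats$PP <- rep(40, 10); beats$interval_s <- rep(1, 10)
  beats$ppg_bp_corr <- rep(0.99, 10)
  flagged <- flag_outlier_beats(beats, ppg = x, fs = fs)
  expect_true(all(!flagged$valid))
  expect_true(all(flagged$reject_reason == "SKEW"))
})

test_that("time windows follow the 100 s / 5 s hop arithmetic", {
  fs <- 50
  nb <- 599
  beats <- tibble::tibble(
    beat = 1:nb, foot_idx = seq(1, by = fs, length.out = nb),
    next_foot_idx = seq(1 + fs, by = fs, length.out = nb),
    interval_s = rep(1, nb), valid = TRUE)
  attr(beats, "fs") <- fs
  w <- make_windows(beats, 600, "time", fs)
  expect_equal(nrow(w), floor((600 - 100) / 5) + 1) # 101
  expect_true(all(w$usable))
  # plant 12 s of invalid beats inside the first window
  beats2 <- beats
  beats2$valid[10:21] <- FALSE
  w2 <- make_windows(beats2, 600, "time", fs)
  expect_false(w2$usable[1])
  # usability is monotone under further corruption
  beats3 <- beats2
  beats3$valid[30:60] <- FALSE
  w3 <- make_windows(beats3, 600, "time", fs)
  expect_true(all(w3$usable <= w2$usable))
})

test_that("beat-count windows chunk valid beats into disjoint hundreds", {
  fs <- 50
  nb <- 250
  beats <- tibble::tibble(
    beat = 1:nb, foot_idx = seq(1, by = fs, length.out = nb),
    next_foot_idx = seq(1 + fs, by = fs, length.out = nb),
    interval_s = rep(1, nb), valid = TRUE)
  attr(beats, "fs") <- fs
  w <- make_windows(beats, nb, "beats", fs)
  expect_equal(nrow(w), 2)
  expect_equal(w$n_valid, c(100, 100))
  expect_lt(w$end_s[1], w$start_s[2] + 1e-9) # disjoint
})

test_that("subject inclusion follows the anthropometric rules", {
  expect_true(filter_subject(list(age = 55, weight = 62, height = 164)))
  expect_false(filter_subject(list(age = 17, weight = 62, height = 164)))
  expect_false(filter_subject(list(age = 40, weight = 150, height = 160)))
  expect_false(filter_subject(list(age = 55, weight = 62, height = 164),
                              sbp_window_medians = c(110, 75)))
  expect_error(filter_subject(list(age = 30, weight = 70)), "height")
})
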