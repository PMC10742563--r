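test_that("pure power-law noise is attributed to the fractal component", {
  for (beta in c(0.5, 1, 1.5)) {
    res <- sapply(1:10, function(s) {
      x <- rnoise_powerlaw(5000, beta, seed = s)
      sp <- irasa_split(x, 50, c(0.5, 10))
      c(fractal_fraction(sp), fit_powerlaw(sp)$beta)
    })
    expect_gte(median(res[1, ]), 95)
    expect_lt(abs(median(res[2, ]) - beta), 0.15)
  }
})

test_that("a pure oscillation is attributed to the oscillatory component", {
  set.seed(9)
  t <- (0:4999) / 50
  x <- sin(2 * pi * 2 * t) + rnorm(5000, 0, 0.01)
  sp <- irasa_split(x, 50, c(0.5, 10))
  expect_lte(fractal_fraction(sp), 10)
  # oscillatory power concentrated within +-0.3 Hz of 2 Hz
  peak <- sp$freq[sp$psd_oscillatory > 0.5 * max(sp$psd_oscillatory)]
  expect_true(all(abs(peak - 2) <= 0.3))
})

test_that("the fractal fraction is scale-invariant and monotone in mixing", {
  set.seed(4)
  x <- rnoise_powerlaw(5000, 1, seed = 4)
  sp1 <- irasa_split(x, 50, c(0.5, 10))
  sp2 <- irasa_split(2 * x, 50, c(0.5, 10))
  expect_equal(fractal_fraction(sp1), fractal_fraction(sp2),
               tolerance = 1e-10)
  # mixture sweep: fraction increases with the fractal weight
  t <- (0:4999) / 50
  osc <- sin(2 * pi * 2 * t)
  fr <- sapply(c(0.1, 0.3, 0.6, 1.2, 2.5), function(w) {
    median(sapply(1:5, function(s) {
      fractal_fraction(irasa_split(osc + w * rnoise_powerlaw(5000, 1,
                                                             seed = s),
                                   50, c(0.5, 10)))
    }))
  })
  expect_true(all(diff(fr) > 0))
})

test_that("power-law fitting is exact on an exact power law", {
  sp <- tibble::tibble(freq = seq(0.5, 10, by = 0.1),
                       psd_fractal = seq(0.5, 10, by = 0.1)^(-1))
  fit <- fit_powerlaw(sp)
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_lt(fit$rel_uncertainty_pct, 1e-6)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-10)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "beta"], 1, tolerance = 1e-10)
})

test_that("white noise fits a flat spectrum", {
  b <- sapply(1:10, function(s) {
    set.seed(s)
    sp <- irasa_split(rnorm(5000), 50, c(0.5, 10))
    fit_powerlaw(sp)$beta
  })
  expect_lt(abs(median(b)), 0.15)
})

test_that("fit uncertainty shrinks with record length", {
  unc <- sapply(c(5000, 50000), function(n) {
    median(sapply(1:5, function(s) {
      sp <- irasa_split(rnoise_powerlaw(n, 1, seed = s), 50, c(0.5, 10))
      fit_powerlaw(sp)$rel_uncertainty_pct
    }))
  })
  expect_lt(unc[2], unc[1])
})

test_that("infeasible bands are rejected with the feasible limit", {
  expect_error(irasa_split(rnorm(1000), 50, c(0.5, 20)), "feasible")
  expect_error(irasa_split(rnorm(50), 50, c(0.5, 10)), "short")
})

test_that("wavelet components localize energy at the matching scale", {
  t <- (0:4999) / 50
  wb <- wavelet_components(sin(2 * pi * 4 * t), 50)
  v <- vapply(wb, var, numeric(1))
  expect_gte(v[["w4.11"]] / sum(v), 0.8)
  # zero signal -> all components zero
  wb0 <- wavelet_components(numeric(5000), 50)
  expect_true(all(vapply(wb0, function(cmp) all(cmp == 0), logical(1))))
  expect_equal(nrow(wb), 5000)
  # white noise: no component dwarfs its neighbours
  set.seed(1)
  vn <- vapply(wavelet_components(rnorm(5000), 50), var, numeric(1))
  ratio <- vn[-length(vn)] / vn[-1]
  expect_true(all(ratio < 3 & ratio > 1 / 3))
  expect_warning(wavelet_components(rnorm(500), 50, c(30, 4.11)), "Nyquist")
})

test_that("simulated fractal observation noise is recovered by IRASA", {
  # ties the generator to the spectral module: when the 1/f observation
  # noise dominates the inter-harmonic continuum, its exponent is recovered
  b <- sapply(1:5, function(s) {
    rec <- simulate_wk4(sim_config(120, seed = s, frac_noise = c(3, 1),
                                   frac_noise_relative = TRUE))
    x <- rec$ppg[rec$t >= 10]
    fit_powerlaw(irasa_split(x[1:5000], 50, c(0.5, 10)))$beta
  })
  expect_lt(abs(median(b) - 1), 0.15)
  # and the fraction grows with the injected noise amplitude
  fr <- sapply(c(0.05, 0.2, 0.6), function(a) {
    r <- simulate_wk4(sim_config(120, seed = 2, frac_noise = c(a, 1),
                                 frac_noise_relative = TRUE))
    fractal_fraction(irasa_split(r$ppg[r$t >= 10][1:5000], 50, c(0.5, 10)))
  })
  expect_true(all(diff(fr) > 0))
})
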