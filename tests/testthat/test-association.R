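test_that("intrasubject correlation recovers exact linear coupling", {
  d <- tibble::tibble(h = 1:30, f = 2 * (1:30) + 1)
  res <- intrasubject_corr(d, "f", "h")
  expect_equal(res$r, 1)
  expect_equal(res$n_windows, 30)
  expect_error(intrasubject_corr(d[1:5, ], "f", "h"), "pairs")
})

test_that("null correlations are calibrated at the 5% level", {
  hits <- sapply(1:500, function(s) {
    set.seed(s)
    abs(cor(rnorm(200), rnorm(200))) < 0.14 # ~2-sided 5% cutoff at n=200
  })
  expect_gte(mean(hits), 0.94)
})

test_that("sensitivity slopes recover planted coefficients", {
  set.seed(2)
  sbp <- runif(100, 90, 140)
  d <- tibble::tibble(SBP = sbp, f = 0.01 * sbp + rnorm(100, 0, 0.05))
  res <- sensitivity_slope(d, "f", "SBP")
  expect_lt(abs(res$slope - 0.01), 2 * res$se)
  # null: CI covers zero in >= 90% of replicates
  cover <- sapply(1:100, function(s) {
    set.seed(s)
    d0 <- tibble::tibble(SBP = runif(50, 90, 140), f = rnorm(50))
    r0 <- sensitivity_slope(d0, "f", "SBP")
    abs(r0$slope) < 1.96 * r0$se
  })
  expect_gte(mean(cover), 0.9)
})

test_that("the median split separates and the rank-sum test rejects", {
  fs <- fluctuation_split(values = 1:10, sigma = 1:10)
  expect_equal(as.character(fs$group), rep(c("low", "high"), each = 5))
  expect_lt(fs$p, 0.01)
  expect_error(fluctuation_split(1:10, rep(1, 10)), "identical")
})

test_that("the rank-sum split has correct size and power", {
  rej <- sapply(1:200, function(s) {
    set.seed(s)
    fluctuation_split(rnorm(40), runif(40))$p < 0.05
  })
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
  pow <- sapply(1:200, function(s) {
    set.seed(s + 10000)
    sig <- c(runif(20, 0, 1), runif(20, 1.01, 2))
    vals <- c(rnorm(20), rnorm(20, 1))
    fluctuation_split(vals, sig)$p < 0.05
  })
  expect_gte(mean(pow), 0.7)
})

test_that("Granger verdicts agree with an independent implementation", {
  skip_if_not_installed("lmtest")
  p <- var_pair(1, "uni")
  v <- granger_classify(p$x, p$y)
  ref <- lmtest::grangertest(p$y ~ p$x, order = v$lag)
  expect_equal(v$p_hemo_to_feature, ref$`Pr(>F)`[2], tolerance = 1e-10)
  expect_equal(as.character(v$category), "UNI_HEMO_TO_FEATURE")
})

test_that("the verdict is always exactly one of the four categories", {
  cats <- sapply(1:20, function(s) {
    p <- var_pair(s, sample(c("uni", "bidir", "null"), 1))
    as.character(granger_classify(p$x, p$y)$category)
  })
  expect_true(all(cats %in% c("UNI_HEMO_TO_FEATURE", "UNI_FEATURE_TO_HEMO",
                              "BIDIRECTIONAL", "NONE")))
  # degenerate input -> NONE with flag
  v <- granger_classify(rep(1, 200), rnorm(200))
  expect_identical(as.character(v$category), "NONE")
  expect_true(v$degenerate)
  expect_error(granger_classify(rnorm(50), rnorm(50)), "paired windows")
  td <- tidy(granger_classify(var_pair(2, "uni")$x, var_pair(2, "uni")$y))
  expect_equal(nrow(td), 2)
})

test_that("nonstationary series are differenced before testing", {
  set.seed(3)
  x <- cumsum(rnorm(300)); y <- cumsum(rnorm(300))
  v <- granger_classify(x, y)
  expect_true(v$differenced)
})

test_that("cohort summaries use median +- sd and count categories", {
  d <- tibble::tibble(subject_id = sprintf("S%d", 1:6),
                      r = rep(0.4, 6),
                      group = rep(c("a", "b"), 3),
                      category = factor(
                        c("NONE", "NONE", "BIDIRECTIONAL",
                          "UNI_HEMO_TO_FEATURE", "NONE", "BIDIRECTIONAL"),
                        levels = c("UNI_HEMO_TO_FEATURE",
                                   "UNI_FEATURE_TO_HEMO", "BIDIRECTIONAL",
                                   "NONE")))
  cs <- cohort_summary(d, "r", "group")
  expect_equal(cs$stats$median, 0.4)
  expect_equal(cs$stats$sd, 0)
  expect_equal(sum(cs$category_counts$n), 6)
  # known shift detected
  set.seed(4)
  d2 <- tibble::tibble(v = c(rnorm(20), rnorm(20, 2)),
                       group = rep(c("a", "b"), each = 20))
  cs2 <- cohort_summary(d2, "v", "group")
  expect_lt(cs2$stats$p_wilcoxon, 0.01)
})
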