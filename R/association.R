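#' Intrasubject feature--hemodynamics correlation
#'
#' Pearson correlation between a per-window complexity (or morphology)
#' series and a per-window hemodynamic series within one subject, with the
#' usual t-distribution p-value. Pairs with missing values are dropped.
#'
#' @param data A data frame with one row per window.
#' @param feature,hemo Column names (strings) of the two series.
#' @param min_pairs Minimum number of complete pairs (default 10).
#' @return A one-row tibble: `feature`, `hemo`, `r`, `p`, `n_windows`.
#' @export
intrasubject_corr <- function(data, feature, hemo, min_pairs = 10) {
  x <- data[[feature]]; y <- data[[hemo]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_pairs)
    stop("fewer than ", min_pairs, " complete window pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(feature = feature, hemo = hemo, r = NA_real_,
                          p = NA_real_, n_windows = length(x)))
  }
  ct <- cor.test(x, y)
  tibble::tibble(feature = feature, hemo = hemo,
                 r = unname(ct$estimate), p = ct$p.value,
                 n_windows = length(x))
}

#' Within-subject sensitivity slope
#'
#' OLS slope of a feature on a hemodynamic target across windows --- the
#' empirical sensitivity (feature units per target unit) --- with its
#' standard error. Conditioning fluctuation levels (e.g. the subject's
#' sigma_CO) can be attached for cross-subject sensitivity analyses.
#'
#' @param data One row per window.
#' @param feature,target Column names (strings).
#' @param min_windows Minimum complete pairs (default 20).
#' @return One-row tibble: `feature`, `target`, `slope`, `se`, `p`,
#'   `n_windows`.
#' @export
sensitivity_slope <- function(data, feature, target, min_windows = 20) {
  x <- data[[target]]; y <- data[[feature]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_windows)
    stop("fewer than ", min_windows, " complete window pairs")
  if (sd(x) == 0)
    return(tibble::tibble(feature = feature, target = target,
                          slope = NA_real_, se = NA_real_, p = NA_real_,
                          n_windows = length(x)))
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  tibble::tibble(feature = feature, target = target,
                 slope = sm[2, 1], se = sm[2, 2], p = sm[2, 4],
                 n_windows = length(x))
}

#' Median split by fluctuation with a rank-sum comparison
#'
#' Splits subjects into "low" and "high" fluctuation groups at the median
#' of `sigma` (ties go to the low group) and compares `values` across the
#' groups with a two-sided Wilcoxon rank-sum test.
#'
#' @param values Per-subject values (e.g. sensitivity slopes).
#' @param sigma Per-subject fluctuation measure (e.g. sigma_CO, L/min).
#' @return A list of class `fluctuation_split`: `group` (factor), medians,
#'   and the Wilcoxon `p`.
#' @export
fluctuation_split <- function(values, sigma) {
  stopifnot(length(values) == length(sigma), length(values) >= 6)
  if (diff(range(sigma, na.rm = TRUE)) == 0)
    stop("all fluctuation values identical; cannot split")
  grp <- factor(ifelse(sigma <= median(sigma, na.rm = TRUE), "low", "high"),
                levels = c("low", "high"))
  wt <- suppressWarnings(wilcox.test(values[grp == "low"],
                                     values[grp == "high"]))
  structure(list(group = grp,
                 median_low = median(values[grp == "low"], na.rm = TRUE),
                 median_high = median(values[grp == "high"], na.rm = TRUE),
                 p = wt$p.value),
            class = "fluctuation_split")
}

#' @export
print.fluctuation_split <- function(x, ...) {
  cat(sprintf("median split: low %.4g (n=%d) vs high %.4g (n=%d), Wilcoxon p = %.3g\n",
              x$median_low, sum(x$group == "low"),
              x$median_high, sum(x$group == "high"), x$p))
  invisible(x)
}

# Augmented Dickey-Fuller t-statistic (constant, k lags of the difference);
# unit root rejected (stationary) when t < -2.86 (5% level, with constant).
adf_stationary <- function(x, k = 4) {
  x <- x[is.finite(x)]
  n <- length(x)
  k <- min(k, max(0, floor(n / 10)))
  dy <- diff(x)
  ylag <- x[(k + 1):(n - 1)]
  dyt <- dy[(k + 1):(n - 1)]
  X <- cbind(1, ylag)
  if (k > 0)
    for (j in seq_len(k)) X <- cbind(X, dy[(k + 1 - j):(n - 1 - j)])
  fit <- lm.fit(X, dyt)
  res <- fit$residuals
  s2 <- sum(res^2) / (length(dyt) - ncol(X))
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(XtXinv)) return(TRUE)
  tstat <- fit$coefficients[2] / sqrt(s2 * XtXinv[2, 2])
  is.finite(tstat) && tstat < -2.86
}

# lagged design matrix: columns x_{t-1}..x_{t-p} aligned to t = (p+1)..n
lag_matrix <- function(x, p) {
  n <- length(x)
  sapply(seq_len(p), function(j) x[(p + 1 - j):(n - j)])
}

granger_f <- function(x, y, p) {
  # does x Granger-cause y at lag order p?
  n <- length(y)
  yt <- y[(p + 1):n]
  Ly <- lag_matrix(y, p)
  Lx <- lag_matrix(x, p)
  full <- lm.fit(cbind(1, Ly, Lx), yt)
  red <- lm.fit(cbind(1, Ly), yt)
  rss1 <- sum(full$residuals^2)
  rss0 <- sum(red$residuals^2)
  df2 <- length(yt) - (2 * p + 1)
  if (df2 <= 0 || rss1 <= 0) return(NA_real_)
  f <- ((rss0 - rss1) / p) / (rss1 / df2)
  stats::pf(f, p, df2, lower.tail = FALSE)
}

# BIC-based lag order for the y-on-(y,x) regression, capped at p_max
select_lag <- function(x, y, p_max) {
  n <- length(y)
  bic <- vapply(seq_len(p_max), function(p) {
    yt <- y[(p_max + 1):n] # common sample across candidate orders
    off <- p_max - p
    Ly <- lag_matrix(y, p)[(off + 1):(n - p), , drop = FALSE]
    Lx <- lag_matrix(x, p)[(off + 1):(n - p), , drop = FALSE]
    fit <- lm.fit(cbind(1, Ly, Lx), yt)
    nn <- length(yt)
    nn * log(sum(fit$residuals^2) / nn) + (2 * p + 1) * log(nn)
  }, numeric(1))
  which.min(bic)
}

#' Granger-causality classification of a hemodynamics--feature pair
#'
#' Bivariate Granger F-tests in both directions on per-window series. Each
#' series failing an augmented unit-root check is differenced (both are
#' differenced if either fails, to keep the pairing). The lag order is the
#' window-hop equivalent of the maximum lag time (50 s / 5 s hop = 10),
#' reduced by BIC when a shorter fit is better. The verdict follows the
#' four-way rule: both directions significant at `alpha` gives
#' `BIDIRECTIONAL`, exactly one gives the corresponding unidirectional
#' category, neither gives `NONE`.
#'
#' @param hemo Per-window hemodynamic series (the putative influencer).
#' @param feature Per-window complexity/feature series.
#' @param max_lag_s Maximum lag time, s (default 50).
#' @param hop_s Window hop, s (default 5).
#' @param alpha Significance level (default 0.05).
#' @param min_windows Minimum paired windows (default 100).
#' @return A one-row tibble of class `granger_verdict`:
#'   `p_hemo_to_feature`, `p_feature_to_hemo`, `lag`, `category`,
#'   `differenced`, `degenerate`.
#' @export
granger_classify <- function(hemo, feature, max_lag_s = 50, hop_s = 5,
                             alpha = 0.05, min_windows = 100) {
  ok <- is.finite(hemo) & is.finite(feature)
  x <- hemo[ok]; y <- feature[ok]
  if (length(x) < min_windows)
    stop("fewer than ", min_windows, " paired windows")
  degenerate <- sd(x) == 0 || sd(y) == 0 ||
    abs(suppressWarnings(cor(x, y))) > 0.9999
  differenced <- FALSE
  if (!degenerate) {
    if (!adf_stationary(x) || !adf_stationary(y)) {
      x <- diff(x); y <- diff(y)
      differenced <- TRUE
      degenerate <- sd(x) == 0 || sd(y) == 0
    }
  }
  p_max <- max(1, round(max_lag_s / hop_s))
  if (degenerate) {
    out <- tibble::tibble(p_hemo_to_feature = NA_real_,
                          p_feature_to_hemo = NA_real_,
                          lag = NA_integer_, category = "NONE",
                          differenced = differenced, degenerate = TRUE)
  } else {
    p_xy <- select_lag(x, y, p_max)
    p_yx <- select_lag(y, x, p_max)
    lag <- max(p_xy, p_yx)
    p1 <- granger_f(x, y, lag) # hemo -> feature
    p2 <- granger_f(y, x, lag) # feature -> hemo
    cat1 <- isTRUE(p1 < alpha); cat2 <- isTRUE(p2 < alpha)
    category <- if (cat1 && cat2) "BIDIRECTIONAL"
    else if (cat1) "UNI_HEMO_TO_FEATURE"
    else if (cat2) "UNI_FEATURE_TO_HEMO"
    else "NONE"
    out <- tibble::tibble(p_hemo_to_feature = p1, p_feature_to_hemo = p2,
                          lag = as.integer(lag), category = category,
                          differenced = differenced, degenerate = FALSE)
  }
  out$category <- factor(out$category,
                         levels = c("UNI_HEMO_TO_FEATURE",
                                    "UNI_FEATURE_TO_HEMO",
                                    "BIDIRECTIONAL", "NONE"))
  class(out) <- c("granger_verdict", class(out))
  out
}

#' @rdname granger_classify
#' @param x A `granger_verdict`.
#' @param ... Unused.
#' @method tidy granger_verdict
#' @export
tidy.granger_verdict <- function(x, ...) {
  tibble::tibble(direction = c("hemo_to_feature", "feature_to_hemo"),
                 p.value = c(x$p_hemo_to_feature, x$p_feature_to_hemo),
                 lag = x$lag, category = as.character(x$category))
}

#' Cohort summary of per-subject association results
#'
#' Median and standard deviation per value column (the robust intersubject
#' summary), optional two-group Wilcoxon rank-sum comparisons, and counts
#' of Granger categories when a `category` column is present.
#'
#' @param data One row per subject.
#' @param value_cols Character vector of numeric columns to summarize.
#' @param group_col Optional column name with two group labels.
#' @return A list of class `cohort_summary` with elements `stats` (tibble:
#'   variable, median, sd, per-group medians and Wilcoxon p when grouped),
#'   and `category_counts` (tibble or NULL).
#' @export
cohort_summary <- function(data, value_cols, group_col = NULL) {
  stopifnot(nrow(data) >= 3)
  rows <- lapply(value_cols, function(cl) {
    v <- data[[cl]]
    out <- tibble::tibble(variable = cl,
                          median = median(v, na.rm = TRUE),
                          sd = sd(v, na.rm = TRUE))
    if (!is.null(group_col)) {
      g <- factor(data[[group_col]])
      stopifnot(nlevels(g) == 2)
      v1 <- v[g == levels(g)[1]]; v2 <- v[g == levels(g)[2]]
      out[[paste0("median_", levels(g)[1])]] <- median(v1, na.rm = TRUE)
      out[[paste0("median_", levels(g)[2])]] <- median(v2, na.rm = TRUE)
      out$p_wilcoxon <- suppressWarnings(wilcox.test(v1, v2))$p.value
    }
    out
  })
  counts <- NULL
  if ("category" %in% names(data)) {
    counts <- dplyr::count(data, .data$category, .drop = FALSE)
  }
  structure(list(stats = dplyr::bind_rows(rows), category_counts = counts),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  print(x$stats)
  if (!is.null(x$category_counts)) print(x$category_counts)
  invisible(x)
}
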