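# Shared fixtures, computed lazily and cached for the whole run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# noiseless steady WK4 record, 60 s
fx_steady <- function() fixture("steady", function() {
  simulate_wk4(sim_config(60, seed = 7, hr_bpm = 60, sv_ml = 70,
                          R0 = 1.0, C1_0 = 1.5, C2_0 = 0.1, L0 = 0.02))
})

# 120 s record with slow C1 drift, no observation noise
fx_c1drift <- function() fixture("c1drift", function() {
  simulate_wk4(sim_config(120, seed = 7, hr_bpm = 72, sv_ml = 70,
                          fluct = list(C1 = c(0.1, 30))))
})

# brute-force oracles (independent O(n^2) R implementations)
bf_sampen <- function(x, m, r) {
  n <- length(x); np <- n - m
  B <- 0; A <- 0
  for (i in 1:(np - 1)) for (j in (i + 1):np) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (A == 0) return(log(B) + log(2))
  -log(A / B)
}

bf_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x); nt <- n - mm + 1
    s <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt)
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

bf_fuzzen <- function(x, m, r, g) {
  phi <- function(mm) {
    n <- length(x); nt <- n - mm
    tp <- sapply(1:nt, function(i) {
      v <- x[i:(i + mm - 1)]; v - mean(v)
    })
    s <- 0
    for (i in 1:(nt - 1)) for (j in (i + 1):nt)
      s <- s + exp(-(max(abs(tp[, i] - tp[, j])) / r)^g)
    2 * s / (nt * (nt - 1))
  }
  log(phi(m)) - log(phi(m + 1))
}

bf_rqa_entr <- function(x, m, tau, eps_frac, lmin) {
  ne <- length(x) - (m - 1) * tau
  emb <- sapply(0:(m - 1), function(q) x[(1 + q * tau):(ne + q * tau)])
  D <- as.matrix(dist(emb, method = "maximum"))
  R <- D <= eps_frac * max(D)
  lens <- c()
  for (k in 1:(ne - 1)) {
    d <- R[cbind(1:(ne - k), (1 + k):ne)]
    rl <- rle(d)
    lens <- c(lens, rl$lengths[rl$values])
  }
  lens <- lens[lens >= lmin]
  if (!length(lens)) return(0)
  p <- as.numeric(table(lens)) / length(lens)
  -sum(p * log(p))
}

# 10-beat toy beat table with planted violations in beats 3, 6, 8
toy_beats <- function() {
  b <- tibble::tibble(
    beat = 1:10,
    foot_idx = seq(1, by = 50, length.out = 10),
    next_foot_idx = seq(51, by = 50, length.out = 10),
    interval_s = rep(1, 10),
    AC = rep(2, 10), DC = rep(1, 10),
    SBP = rep(120, 10), DBP = rep(80, 10), MAP = rep(93, 10),
    PP = rep(40, 10), ppg_bp_corr = rep(0.99, 10),
    co_mean = rep(5, 10))
  b$PP[3] <- 10
  b$interval_s[6] <- 1.8
  b$ppg_bp_corr[8] <- 0.5
  attr(b, "fs") <- 50
  b
}

# synthetic VAR pairs for Granger calibration
var_pair <- function(seed, kind = c("uni", "bidir", "null"), n = 500) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "null") {
    return(list(x = as.numeric(arima.sim(list(ar = 0.6), n)),
                y = as.numeric(arima.sim(list(ar = 0.6), n))))
  }
  if (kind == "uni") {
    x <- as.numeric(arima.sim(list(ar = 0.6), n))
    e <- rnorm(n); y <- numeric(n)
    for (t in 4:n) y[t] <- 0.3 * y[t - 1] + 0.8 * x[t - 3] + e[t]
    return(list(x = x, y = y))
  }
  ex <- rnorm(n); ey <- rnorm(n)
  x <- numeric(n); y <- numeric(n)
  x[1:3] <- rnorm(3); y[1:3] <- rnorm(3)
  for (t in 4:n) {
    x[t] <- 0.3 * x[t - 1] + 0.5 * y[t - 2] + ex[t]
    y[t] <- 0.3 * y[t - 1] + 0.5 * x[t - 3] + ey[t]
  }
  list(x = x, y = y)
}
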