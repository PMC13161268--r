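fake_markers <- function(n = 100, fs = 300, xcol = function(nm) 0) {
  d <- data.frame(t_s = (seq_len(n) - 1) / fs)
  for (nm in c("head", "shoulder", "greater_trochanter", "knee", "ankle",
               "toe")) {
    d[[paste0(nm, "_x")]] <- rep(xcol(nm), length.out = n)
    d[[paste0(nm, "_y")]] <- 0
  }
  d
}

test_that("marker COM is a mass-fraction-weighted mean relative to the ankle", {
  # all markers stacked over the ankle
  expect_equal(com_from_markers(fake_markers()), rep(0, 100))
  # two-segment toy: 0.6 of the mass with its segment COM at +10 mm,
  # 0.4 at -5 mm -> +4 mm
  seg <- segment_model(mass_fractions = c(shank = 0, thigh = 0, hat = 0.6,
                                          foot = 0.4),
                       com_fractions = c(shank = 0, thigh = 0, hat = 1,
                                         foot = 1))
  mk <- fake_markers(xcol = function(nm)
    switch(nm, head = 10, toe = -5, 0))
  expect_equal(com_from_markers(mk, seg), rep(0.6 * 10 + 0.4 * (-5), 100))
  # invariant enforcement and named-channel errors
  expect_error(segment_model(mass_fractions = c(shank = 0.2, thigh = 0.2,
                                                hat = 0.2, foot = 0.2)),
               "sum to 1")
  bad <- fake_markers()
  bad$ankle_x <- NULL
  expect_error(com_from_markers(bad), "ankle_x")
})

test_that("Butterworth filters have unit DC gain and -3 dB at the cutoff", {
  fs <- 300
  t <- seq(0, 20, by = 1 / fs)
  expect_equal(butterworth(rep(2.5, length(t)), "low", 5, fs = fs),
               rep(2.5, length(t)), tolerance = 1e-6)
  # single-pass amplitude at the cutoff is 1/sqrt(2) within 2%
  x <- sin(2 * pi * 5 * t)
  y <- butterworth(x, "low", 5, fs = fs, zero_phase = FALSE)
  steady <- t > 5
  ratio <- max(abs(y[steady])) / 1
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.02)
  # constants die under a high-pass
  hp <- butterworth(rep(1, length(t)), "high", 1, fs = fs)
  expect_lt(max(abs(hp[steady])), 1e-3)
  expect_error(butterworth(x, "low", 200, fs = fs), "Nyquist")
})

test_that("five-point differentiation is exact through degree-4 polynomials", {
  dt <- 0.01
  t <- seq(0, 1, by = dt)
  expect_equal(five_point_velocity(3 * t + 1, dt), rep(3, length(t)),
               tolerance = 1e-10)
  expect_equal(five_point_velocity(rep(7, length(t)), dt),
               rep(0, length(t)), tolerance = 1e-12)
  v4 <- five_point_velocity(t^4, dt)
  i <- 3:(length(t) - 2)
  expect_equal(v4[i], 4 * t[i]^3, tolerance = 1e-8)
  # edge stencils are exact on cubics (same formal order)
  v3 <- five_point_velocity(t^3, dt)
  expect_equal(v3, 3 * t^2, tolerance = 1e-8)
  expect_error(five_point_velocity(1:4, dt), "too short")
})

test_that("EMG envelope chain demodulates an interference-pattern signal", {
  fs <- 300
  t <- seq(0, 12, by = 1 / fs)
  expect_equal(emg_envelope(rep(0, length(t)), mvc = 1), rep(0, length(t)),
               tolerance = 1e-9)
  expect_error(emg_envelope(rep(0, 10), mvc = 0), "positive")
  # amplitude-modulated carrier: the envelope tracks the modulation shape
  # within 5% after the transient (up to the rectification gain)
  mod <- 1 + 0.5 * sin(2 * pi * 0.4 * t)
  raw <- mod * sin(2 * pi * 100 * t)
  env <- emg_envelope(raw, mvc = 100)
  steady <- t > 2 & t < 10
  rel <- env[steady] / mean(env[steady])
  want <- mod[steady] / mean(mod[steady])
  expect_lt(max(abs(rel - want)), 0.05)
})

test_that("pooled t-test reproduces the textbook formula", {
  same <- c(1, 2, 3, 4)
  r0 <- student_t(same, same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  r <- student_t(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(t_hand, 4), tolerance = 1e-12)
  expect_equal(r$direction, -1)
  # 20 + 20 observations give df = 38
  expect_equal(student_t(rnorm(20), rnorm(20))$df, 38)
})

test_that("ANOVA decompositions match a hand sums-of-squares computation", {
  set.seed(5)
  d <- expand.grid(cue = c("no", "yes"), stage = 1:6, rep = 1:5)
  d$y <- 0.2 * (d$cue == "yes") + 0.05 * d$stage + rnorm(nrow(d), sd = 0.3)
  res <- anova_cue_stage(d$y, d$cue, d$stage)
  # manual main-effects decomposition for the balanced table
  g <- mean(d$y)
  ssa <- sum(tapply(d$y, d$cue, function(v) length(v) * (mean(v) - g)^2))
  ssb <- sum(tapply(d$y, d$stage, function(v) length(v) * (mean(v) - g)^2))
  sst <- sum((d$y - g)^2)
  sse <- sst - ssa - ssb
  dfe <- nrow(d) - 1 - 1 - 5
  expect_equal(res$cue$statistic, (ssa / 1) / (sse / dfe), tolerance = 1e-9)
  expect_equal(res$stage$statistic, (ssb / 5) / (sse / dfe), tolerance = 1e-9)
  expect_equal(res$cue$df, c(1, dfe))
  # near-identical groups are not significant
  set.seed(6)
  d0 <- expand.grid(cue = c("no", "yes"), stage = 1:6, rep = 1:5)
  d0$y <- 1 + rnorm(nrow(d0), sd = 1e-4)
  res0 <- anova_cue_stage(d0$y, d0$cue, d0$stage)
  expect_gt(res0$cue$p, 0.05)
  # a large constructed stage shift is detected by the one-way ANOVA
  y1 <- rep(1:4, each = 10) + rnorm(40, sd = 0.1)
  expect_lt(anova_oneway(y1, rep(1:4, each = 10))$p, 0.001)
})

test_that("OLS regression with confidence band matches the normal equations", {
  x <- c(0.5, 1.2, 1.9, 2.3, 3.1, 3.8, 4.2, 5.0, 5.7, 6.4)
  set.seed(9)
  y <- 1.5 + 0.8 * x + rnorm(10, sd = 0.3)
  r <- regression_with_ci(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(r$slope, slope_hand, tolerance = 1e-12)
  resid <- y - (mean(y) - slope_hand * mean(x)) - slope_hand * x
  r2_hand <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  expect_equal(r$r_squared, r2_hand, tolerance = 1e-12)
  se_slope <- sqrt(sum(resid^2) / 8 / sxx)
  expect_equal(r$p, 2 * pt(-abs(slope_hand / se_slope), 8),
               tolerance = 1e-12)
  expect_true(all(r$band$lower <= r$band$fit & r$band$fit <= r$band$upper))
  # exactly collinear points give R^2 = 1; pure noise gives R^2 near 0
  expect_equal(suppressWarnings(regression_with_ci(x, 2 * x - 1)$r_squared), 1)
  set.seed(10)
  y0 <- rnorm(200)
  x0 <- rnorm(200)
  expect_lt(regression_with_ci(x0, y0)$r_squared, 0.05)
})

test_that("phase portraits preserve oscillation geometry", {
  fs <- 300
  t <- seq(0, 10, by = 1 / fs)
  com <- 61 + 10 * sin(2 * pi * 0.5 * t)
  pp <- phase_portrait(com, dt = 1 / fs, t = t, cs = 2, fs = 8)
  expect_true(all(pp$t >= 2 & pp$t <= 8))
  # velocity amplitude = omega * position amplitude within 2%
  expect_lt(abs(max(abs(pp$velocity)) - 2 * pi * 0.5 * 10) /
              (2 * pi * 0.5 * 10), 0.02)
  # constant COM collapses to a single point at zero velocity
  pp0 <- phase_portrait(rep(61, length(t)), dt = 1 / fs, t = t)
  expect_lt(max(abs(pp0$velocity)), 1e-6)
  expect_lt(max(abs(pp0$position - 61)), 1e-6)
  # linear drift preserves the cycle while translating it
  ppd <- phase_portrait(com + 2 * t, dt = 1 / fs, t = t, cs = 2, fs = 8)
  expect_equal(diff(range(ppd$velocity)), diff(range(pp$velocity)),
               tolerance = 0.05)
  expect_gt(ppd$position[length(ppd$position)] - ppd$position[1], 8)
})

test_that("first-peak latency finds the first qualifying local maximum", {
  fs <- 300
  t <- seq(0, 3, by = 1 / fs)
  onset <- 1
  bump <- function(at, amp) amp * exp(-0.5 * ((t - onset - at) / 0.02)^2)
  gc <- 8 + bump(0.085, 30)
  expect_equal(first_peak_latency(gc, t, onset), 85, tolerance = 5)
  # monotone rise has no local maximum inside the window
  expect_true(is.na(first_peak_latency(8 + pmax(t - onset, 0) * 50,
                                       t, onset)))
  # two bumps: the first, not the largest, wins
  gc2 <- 8 + bump(0.060, 20) + bump(0.140, 40)
  expect_equal(first_peak_latency(gc2, t, onset), 60, tolerance = 5)
  # sub-threshold peaks are ignored
  expect_true(is.na(first_peak_latency(8 + bump(0.085, 3), t, onset)))
})
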