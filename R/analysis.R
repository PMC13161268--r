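#' Segment model for marker-based centre-of-mass estimation
#'
#' Four sagittal segments defined by marker pairs (from, to):
#' shank (ankle to knee), thigh (knee to greater trochanter), HAT
#' (greater trochanter to head) and foot (ankle to toe). Each segment
#' contributes its mass fraction at `from + com_fraction * (to - from)`.
#' Default fractions follow a standard anthropometric table; mass
#' fractions must sum to 1.
#'
#' @param mass_fractions named numeric (shank, thigh, hat, foot), sum 1.
#' @param com_fractions named numeric, COM location along each marker pair
#'   measured from the `from` marker.
#' @return an object of class `segment_model`.
#' @export
segment_model <- function(mass_fractions = c(shank = 0.093, thigh = 0.200,
                                             hat = 0.678, foot = 0.029),
                          com_fractions = c(shank = 0.567, thigh = 0.567,
                                            hat = 0.500, foot = 0.500)) {
  nm <- c("shank", "thigh", "hat", "foot")
  stopifnot(setequal(names(mass_fractions), nm),
            setequal(names(com_fractions), nm))
  if (abs(sum(mass_fractions) - 1) > 1e-9)
    stop("segment mass fractions must sum to 1")
  structure(list(mass_fractions = mass_fractions[nm],
                 com_fractions = com_fractions[nm]),
            class = "segment_model")
}

#' Segment model consistent with a simulated two-link body
#'
#' Computes mass and COM fractions such that the marker-based COM of a
#' rendering of the two-link model ([markers_from_sim()]) reproduces the
#' model COM exactly: the foot carries zero mass, the HAT fraction places
#' its COM at the body's link-2 COM, and the shank/thigh fractions are
#' solved so the leg contribution matches link 1.
#'
#' @param body a [body_params()].
#' @param geom marker geometry as produced by [marker_geometry()].
#' @return a [segment_model()].
#' @export
segment_model_for_body <- function(body = body_params(),
                                   geom = marker_geometry(body)) {
  M <- body$total_mass
  w1 <- body$link1_mass / M
  w2 <- body$link2_mass / M
  # HAT: head marker at geom$head_u * link2 direction from the hip
  f_hat <- body$link2_com / geom$head_u
  # legs: split link-1 mass between shank (ankle-knee) and thigh
  # (knee-trochanter) in standard proportion, then solve the shared COM
  # fraction f so the lever arms reproduce link1_com
  ws <- w1 * 0.093 / 0.293
  wt <- w1 * 0.200 / 0.293
  kf <- geom$knee_u / body$link1_length       # knee position fraction
  # ws*kf*f + wt*(kf + (1-kf)*f) = w1 * link1_com/link1_length
  target <- w1 * body$link1_com / body$link1_length
  f <- (target - wt * kf) / (ws * kf + wt * (1 - kf))
  segment_model(mass_fractions = c(shank = ws, thigh = wt, hat = w2, foot = 0),
                com_fractions = c(shank = f, thigh = f, hat = f_hat,
                                  foot = 0.5))
}

required_markers <- c("head", "shoulder", "greater_trochanter", "knee",
                      "ankle", "toe")

marker_cols <- function(markers) {
  miss <- setdiff(as.vector(outer(required_markers, c("x", "y"),
                                  function(a, b) paste(a, b, sep = "_"))),
                  names(markers))
  if (length(miss))
    stop("missing marker channel(s): ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Whole-body COM from sagittal markers
#'
#' Segment COMs are interpolated along their marker pairs and combined by
#' the segment mass fractions; the result is reported relative to the
#' ankle marker, anterior positive, in mm.
#'
#' @param markers data.frame with columns `t_s` and `<marker>_x`,
#'   `<marker>_y` (mm) for head, shoulder, greater_trochanter, knee,
#'   ankle, toe.
#' @param seg a [segment_model()].
#' @return numeric COM series (mm), one value per row of `markers`.
#' @export
com_from_markers <- function(markers, seg = segment_model()) {
  stopifnot(inherits(seg, "segment_model"))
  marker_cols(markers)
  segx <- function(from, to, f)
    (1 - f) * markers[[paste0(from, "_x")]] + f * markers[[paste0(to, "_x")]]
  f <- seg$com_fractions
  w <- seg$mass_fractions
  x <- w["shank"] * segx("ankle", "knee", f["shank"]) +
       w["thigh"] * segx("knee", "greater_trochanter", f["thigh"]) +
       w["hat"]   * segx("greater_trochanter", "head", f["hat"]) +
       w["foot"]  * segx("ankle", "toe", f["foot"])
  unname(x - markers$ankle_x)
}

#' Fourth-order Butterworth filter
#'
#' Zero-phase (forward-backward) filtering is the default so that latency
#' measures are unbiased; note the forward-backward pass doubles the
#' effective order. Single-pass filtering is available with
#' `zero_phase = FALSE`.
#'
#' @param x numeric series.
#' @param kind "low" or "high".
#' @param cutoff cutoff frequency (Hz), below the Nyquist frequency.
#' @param fs sampling rate (Hz).
#' @param order filter order.
#' @param zero_phase logical.
#' @return filtered series.
#' @export
butterworth <- function(x, kind = c("low", "high"), cutoff, fs = 300,
                        order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (fs / 2),
                       type = if (kind == "low") "low" else "high")
  if (!zero_phase) return(as.numeric(signal::filter(bf, x)))
  # forward-backward pass over an odd-reflection padded copy with
  # steady-state initial conditions, so constants pass exactly and edges
  # stay clean
  filt1 <- function(z) {
    y_ss <- z[1] * sum(bf$b) / sum(bf$a)
    as.numeric(signal::filter(bf$b, bf$a, z,
                              init.x = rep(z[1], length(bf$b) - 1),
                              init.y = rep(y_ss, length(bf$a) - 1)))
  }
  n <- length(x)
  np <- min(n - 1, ceiling(3 * fs / cutoff))
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - np)]
  xp <- c(left, x, right)
  y <- rev(filt1(rev(filt1(xp))))
  y[(np + 1):(np + n)]
}

#' Five-point numerical differentiation
#'
#' Central five-point stencil
#' `(x[i-2] - 8 x[i-1] + 8 x[i+1] - x[i+2]) / (12 dt)` in the interior
#' (exact through degree-4 polynomials); one-sided five-point stencils of
#' the same order at the two samples on each edge.
#'
#' @param x numeric series, length >= 5.
#' @param dt sample interval (s).
#' @return derivative series of the same length.
#' @export
five_point_velocity <- function(x, dt) {
  n <- length(x)
  if (n < 5) stop("series too short for five-point differentiation")
  v <- numeric(n)
  i <- 3:(n - 2)
  v[i] <- (x[i - 2] - 8 * x[i - 1] + 8 * x[i + 1] - x[i + 2]) / (12 * dt)
  fwd <- function(k, s) # one-sided stencils, s = +1 forward, -1 backward
    s * sum(c(-25, 48, -36, 16, -3) * x[k + s * (0:4)]) / (12 * dt)
  off <- function(k, s)
    s * sum(c(-3, -10, 18, -6, 1) * x[k + s * (-1:3)]) / (12 * dt)
  v[1] <- fwd(1, 1); v[2] <- off(2, 1)
  v[n] <- fwd(n, -1); v[n - 1] <- off(n - 1, -1)
  v
}

#' EMG envelope in percent MVC
#'
#' 1-Hz high-pass, full-wave rectification, 10-Hz low-pass (both
#' fourth-order Butterworth), then normalisation to the maximal voluntary
#' contraction reference. Rectification between the two filters is
#' required for a meaningful envelope of an interference-pattern signal.
#'
#' @param raw raw EMG series.
#' @param mvc MVC reference (same units as `raw`), positive.
#' @param fs sampling rate (Hz).
#' @param zero_phase logical, forwarded to [butterworth()].
#' @return envelope in %MVC (values above 100 are allowed).
#' @export
emg_envelope <- function(raw, mvc, fs = 300, zero_phase = TRUE) {
  if (!is.numeric(mvc) || mvc <= 0) stop("mvc must be positive")
  hp <- butterworth(raw, "high", 1, fs = fs, zero_phase = zero_phase)
  lp <- butterworth(abs(hp), "low", 10, fs = fs, zero_phase = zero_phase)
  100 * lp / mvc
}

stat_result <- function(test, statistic, df, p, direction = NA_real_,
                        extra = NULL) {
  structure(c(list(test = test, statistic = statistic, df = df, p = p,
                   direction = direction), extra),
            class = "stat_result")
}

#' Two-sided pooled-variance Student's t-test
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return a `stat_result` with `statistic`, `df = n1 + n2 - 2`, `p`, and
#'   `direction` (sign of `mean(a) - mean(b)`).
#' @export
student_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ht <- stats::t.test(a, b, var.equal = TRUE)
  stat_result("two-sample t (pooled)", unname(ht$statistic),
              unname(ht$parameter), ht$p.value,
              direction = sign(mean(a) - mean(b)))
}

#' Two-way fixed-effects ANOVA (cue x stage)
#'
#' Main effects only by default, mirroring analyses that report the two
#' factor p-values; the interaction can be included with
#' `interaction = TRUE`.
#'
#' @param value numeric response.
#' @param cue,stage factors (or coercible).
#' @param interaction include the cue:stage interaction term.
#' @return list of `stat_result`, one per factor (and interaction).
#' @export
anova_cue_stage <- function(value, cue, stage, interaction = FALSE) {
  d <- data.frame(value = value, cue = factor(cue), stage = factor(stage))
  form <- if (interaction) value ~ cue * stage else value ~ cue + stage
  tab <- summary(stats::aov(form, data = d))[[1]]
  terms <- rownames(tab)
  keep <- seq_len(nrow(tab) - 1)           # drop Residuals
  out <- lapply(keep, function(i)
    stat_result(paste("ANOVA:", trimws(terms[i])), tab[i, "F value"],
                c(tab[i, "Df"], tab[nrow(tab), "Df"]), tab[i, "Pr(>F)"]))
  names(out) <- trimws(terms[keep])
  out
}

#' One-way fixed-effects ANOVA
#'
#' @param value numeric response.
#' @param group factor (or coercible).
#' @return a `stat_result` with F, `df = c(between, within)` and p.
#' @export
anova_oneway <- function(value, group) {
  d <- data.frame(value = value, group = factor(group))
  tab <- summary(stats::aov(value ~ group, data = d))[[1]]
  stat_result("one-way ANOVA", tab[1, "F value"],
              c(tab[1, "Df"], tab[2, "Df"]), tab[1, "Pr(>F)"])
}

#' Ordinary least-squares regression with a 95% confidence band
#'
#' @param x,y numeric vectors, length >= 3.
#' @param band_at x values at which to evaluate the pointwise 95%
#'   confidence band of the mean response (default: sorted `x`).
#' @return list with `slope`, `intercept`, `r_squared`, `p` (two-sided
#'   slope test), `band` (data.frame x, fit, lower, upper) and the `lm`
#'   fit object.
#' @export
regression_with_ci <- function(x, y, band_at = sort(x)) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::predict(fit, newdata = data.frame(x = band_at),
                       interval = "confidence", level = 0.95)
  p_slope <- if (nrow(sm$coefficients) >= 2) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared, p = p_slope,
       band = data.frame(x = band_at, fit = ci[, "fit"],
                         lower = ci[, "lwr"], upper = ci[, "upr"]),
       fit = fit)
}

#' COM phase portrait over the cue period
#'
#' The COM position series is low-pass filtered at 5 Hz (fourth-order
#' Butterworth, zero-phase by default), differentiated with the five-point
#' stencil, and clipped to `[cs, fs]`; an activity channel can be
#' co-registered for colouring.
#'
#' @param com COM series (mm).
#' @param dt sample interval (s).
#' @param t optional time base (s); default starts at 0.
#' @param cs,fs window bounds (s); default full series.
#' @param activity optional series aligned with `com`.
#' @param fs_rate sampling rate override (Hz); default `1/dt`.
#' @param zero_phase logical.
#' @return data.frame with `t`, `position` (mm), `velocity` (mm/s) and,
#'   when supplied, `activity`.
#' @export
phase_portrait <- function(com, dt, t = (seq_along(com) - 1) * dt,
                           cs = t[1], fs = t[length(t)], activity = NULL,
                           fs_rate = 1 / dt, zero_phase = TRUE) {
  stopifnot(length(com) == length(t))
  pos <- butterworth(com, "low", 5, fs = fs_rate, zero_phase = zero_phase)
  vel <- five_point_velocity(pos, dt)
  keep <- t >= cs & t <= fs
  out <- data.frame(t = t[keep], position = pos[keep], velocity = vel[keep])
  if (!is.null(activity)) {
    stopifnot(length(activity) == length(com))
    out$activity <- activity[keep]
  }
  out
}

#' Latency of the first GC activity peak after tilt onset
#'
#' First local maximum after onset whose height exceeds the pre-onset
#' baseline mean by a prominence threshold (default 5 %MVC). Returns `NA`
#' when no qualifying peak exists (a reportable missing value, not an
#' error).
#'
#' @param gc envelope series (%MVC).
#' @param t time base (s).
#' @param onset tilt onset time (s).
#' @param window search window length after onset (s).
#' @param prominence required height above baseline (%MVC).
#' @param baseline_window pre-onset span used for the baseline mean (s).
#' @return latency (ms) or `NA_real_`.
#' @export
first_peak_latency <- function(gc, t, onset, window = 1,
                               prominence = 5, baseline_window = 1) {
  stopifnot(length(gc) == length(t))
  in_win <- which(t >= onset & t <= onset + window)
  if (length(in_win) < 3) stop("empty search window after onset")
  base <- mean(gc[t >= onset - baseline_window & t < onset])
  thr <- base + prominence
  y <- gc[in_win]
  is_peak <- c(FALSE, y[2:(length(y) - 1)] > y[1:(length(y) - 2)] &
                      y[2:(length(y) - 1)] >= y[3:length(y)], FALSE)
  hit <- which(is_peak & y > thr)
  if (!length(hit)) return(NA_real_)
  1000 * (t[in_win[hit[1]]] - onset)
}
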