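#' Marker placement geometry for rendering the two-link body
#'
#' Fixed marker offsets used when rendering simulated (or synthetic)
#' standing: knee halfway up link 1, shoulder and head on link 2, toe
#' 150 mm anterior of the ankle on the floor frame. Only the relative
#' geometry matters for COM estimation.
#'
#' @param body a [body_params()].
#' @return list with `knee_u`, `shoulder_u`, `head_u` (m along the links)
#'   and `toe_mm` (mm along the floor).
#' @export
marker_geometry <- function(body = body_params()) {
  list(knee_u = 0.5 * body$link1_length,
       shoulder_u = 0.55,
       head_u = 2 * body$link2_com,
       toe_mm = 150)
}

#' Render a simulated trial as a 300-Hz sagittal marker set
#'
#' Forward kinematics of the two-link model to the six body markers
#' (ankle at the origin, knee on link 1, greater trochanter at the hip,
#' shoulder and head on link 2, toe on the floor frame), resampled from
#' the plant rate to 300 Hz by linear interpolation, with optional
#' Gaussian marker noise.
#'
#' @param tr a [run_trial()] result.
#' @param body a [body_params()]; defaults to the trial's scenario body.
#' @param noise_sd marker noise SD (mm).
#' @param fs_out output sampling rate (Hz).
#' @param seed seed for the marker noise.
#' @return data.frame with `t_s` and `<marker>_x`, `<marker>_y` columns
#'   (mm), 300-Hz rows.
#' @export
markers_from_sim <- function(tr, body = tr$scenario$body, noise_sd = 0,
                             fs_out = 300, seed = 1) {
  s <- tr$series
  tt <- seq(s$t[1], s$t[nrow(s)], by = 1 / fs_out)
  th_a <- stats::approx(s$t, s$theta_ankle, tt)$y
  th_h <- stats::approx(s$t, s$theta_hip, tt)$y
  phi <- stats::approx(s$t, s$phi, tt)$y
  render_markers(tt, th_a, th_h, phi, body, noise_sd, seed)
}

render_markers <- function(tt, th_a, th_h, phi, body, noise_sd, seed) {
  g <- marker_geometry(body)
  a1 <- th_a + phi
  a2 <- a1 + th_h
  mm <- 1000
  hip_x <- -body$link1_length * sin(a1) * mm
  hip_y <- body$link1_length * cos(a1) * mm
  pos <- list(
    ankle = cbind(0, 0)[rep(1, length(tt)), , drop = FALSE],
    knee = cbind(-g$knee_u * sin(a1), g$knee_u * cos(a1)) * mm,
    greater_trochanter = cbind(hip_x / mm, hip_y / mm) * mm,
    shoulder = cbind(hip_x - g$shoulder_u * sin(a2) * mm,
                     hip_y + g$shoulder_u * cos(a2) * mm),
    head = cbind(hip_x - g$head_u * sin(a2) * mm,
                 hip_y + g$head_u * cos(a2) * mm),
    toe = cbind(g$toe_mm * cos(phi), g$toe_mm * sin(phi))
  )
  out <- data.frame(t_s = tt)
  set.seed(as.integer(seed %% 2147483647))
  for (nm in names(pos)) {
    x <- pos[[nm]][, 1]
    y <- pos[[nm]][, 2]
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(tt), sd = noise_sd)
      y <- y + stats::rnorm(length(tt), sd = noise_sd)
    }
    out[[paste0(nm, "_x")]] <- x
    out[[paste0(nm, "_y")]] <- y
  }
  out
}

#' Render simulated muscle activity as a 300-Hz EMG record
#'
#' The activation series is expressed in %MVC (activation 1 = 100%),
#' resampled to 300 Hz, and stored both as an envelope (with optional
#' additive Gaussian noise, floored at zero) and as a rectifiable raw
#' carrier (envelope-modulated white noise scaled so that the analysis
#' envelope chain recovers the activation). The MVC reference of the raw
#' channel is 1.
#'
#' @param tr a [run_trial()] result.
#' @param noise_sd envelope noise SD (%MVC).
#' @param fs_out output sampling rate (Hz).
#' @param seed seed for noise and carrier.
#' @return data.frame with `t_s`, `TA`, `GC` (raw carrier, MVC units),
#'   `TA_env`, `GC_env` (%MVC envelopes); attribute `mvc = 1`.
#' @export
emg_from_sim <- function(tr, noise_sd = 0, fs_out = 300, seed = 1) {
  s <- tr$series
  tt <- seq(s$t[1], s$t[nrow(s)], by = 1 / fs_out)
  ta <- 100 * stats::approx(s$t, s$a_TA, tt)$y
  gc <- 100 * stats::approx(s$t, s$a_GC, tt)$y
  render_emg(tt, ta, gc, noise_sd, seed)
}

render_emg <- function(tt, ta_pct, gc_pct, noise_sd, seed) {
  set.seed(as.integer(seed %% 2147483647))
  n <- length(tt)
  env <- function(pct) if (noise_sd > 0)
    pmax(pct + stats::rnorm(n, sd = noise_sd), 0) else pct
  ta_env <- env(ta_pct)
  gc_env <- env(gc_pct)
  # carrier with E|z| = 1 so rectification recovers the envelope scale
  carrier <- function(e) (e / 100) * stats::rnorm(n) * sqrt(pi / 2)
  out <- data.frame(t_s = tt, TA = carrier(ta_env), GC = carrier(gc_env),
                    TA_env = ta_env, GC_env = gc_env)
  attr(out, "mvc") <- 1
  out
}

#' Ten-hertz display filtering of simulated GC activity
#'
#' The same fourth-order 10-Hz low-pass applied to experimental envelopes,
#' used when inspecting simulated GC traces (e.g. the reflex window).
#'
#' @param tr a [run_trial()] result.
#' @return data.frame `t`, `gc_pct` (filtered GC activity, % of maximum).
#' @export
gc_display <- function(tr) {
  s <- tr$series
  fs <- 1 / (s$t[2] - s$t[1])
  data.frame(t = s$t,
             gc_pct = butterworth(100 * s$a_GC, "low", 10, fs = fs))
}

#' Specification of a synthetic marker/EMG cohort
#'
#' Emulates the recording protocol: 30-s trials at 300 Hz, a 4-degree
#' floor tilt over 0.81 s starting at 20 s, and (cue condition only) an
#' auditory cue 2-3 s before the tilt after which the COM drifts forward
#' by `com_shift_mm` while the GC envelope ramps at `gc_slope`. Quiet
#' sway is a band-limited oscillation (period 3-5 s, amplitude 3-5 mm)
#' plus slow filtered noise.
#'
#' @param n_subjects number of subjects.
#' @param n_trials trials per condition per subject (30, staged 6 x 5).
#' @param duration trial length (s).
#' @param tilt_time tilt onset (s).
#' @param tilt_duration ramp duration (s).
#' @param tilt_deg tilt magnitude (degrees).
#' @param cue_lead_range cue lead time before the tilt (s), sampled
#'   uniformly per trial.
#' @param com_shift_mm mean cue-conditioned forward COM drift (mm); 0
#'   gives a null generator.
#' @param gc_slope mean cue-period GC envelope slope (%MVC/s).
#' @param subject_sd_mm,trial_sd_mm between-subject and between-trial SD
#'   of the injected shift (mm).
#' @param sway_amp_mm,sway_period_s ranges (length-2) of the sway
#'   oscillation amplitude and period.
#' @param marker_noise_sd marker noise SD (mm).
#' @param emg_noise_sd envelope noise SD (%MVC).
#' @param gc_burst_latency_s,gc_burst_amp post-tilt GC burst placement (s
#'   after onset) and amplitude (%MVC).
#' @param body a [body_params()] for the forward kinematics.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(n_subjects = 10, n_trials = 30, duration = 30,
                       tilt_time = 20, tilt_duration = 0.81, tilt_deg = 4,
                       cue_lead_range = c(2, 3),
                       com_shift_mm = 25, gc_slope = 3,
                       subject_sd_mm = 8, trial_sd_mm = 4,
                       sway_amp_mm = c(3, 5), sway_period_s = c(3, 5),
                       marker_noise_sd = 0.5, emg_noise_sd = 1,
                       gc_burst_latency_s = 0.085, gc_burst_amp = 35,
                       body = body_params()) {
  stopifnot(com_shift_mm >= 0, gc_slope >= 0, n_trials >= 1,
            tilt_time + tilt_duration < duration,
            cue_lead_range[1] <= cue_lead_range[2])
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate one synthetic standing trial
#'
#' Joint-angle series = quiet-sway oscillation (+ cue-conditioned ankle
#' ramp producing the requested COM drift, cue condition only) + tilt
#' response; markers by forward kinematics plus Gaussian noise; EMG as
#' envelope plus rectified-noise carrier with a GC ramp (cue) and a
#' post-tilt burst.
#'
#' @param spec a [synth_spec()].
#' @param condition "cue" or "no_cue".
#' @param seed integer seed (fully determines the trial).
#' @param com_shift_mm,gc_slope per-trial effect overrides; default the
#'   spec means.
#' @return list with `markers`, `emg`, `events` (data.frame name, t_s) and
#'   `truth` (injected delta_com, gc_slope, cue/tilt times).
#' @export
synth_trial <- function(spec, condition = c("cue", "no_cue"), seed = 1,
                        com_shift_mm = spec$com_shift_mm,
                        gc_slope = spec$gc_slope) {
  condition <- match.arg(condition)
  set.seed(as.integer(seed %% 2147483647))
  fs <- 300
  tt <- seq(0, spec$duration, by = 1 / fs)
  n <- length(tt)
  cue_lead <- stats::runif(1, spec$cue_lead_range[1], spec$cue_lead_range[2])
  cs <- spec$tilt_time - cue_lead
  fs_time <- spec$tilt_time
  tilt_end <- spec$tilt_time + spec$tilt_duration

  # floor ramp
  phi_max <- spec$tilt_deg * pi / 180
  phi <- pmin(pmax((tt - spec$tilt_time) / spec$tilt_duration, 0), 1) * phi_max

  # COM trajectory (mm, about the baseline posture)
  amp <- stats::runif(1, spec$sway_amp_mm[1], spec$sway_amp_mm[2])
  per <- stats::runif(1, spec$sway_period_s[1], spec$sway_period_s[2])
  sway <- amp * sin(2 * pi * tt / per + stats::runif(1, 0, 2 * pi)) +
    butterworth(stats::rnorm(n, sd = 6), "low", 0.8, fs = fs)
  drift <- if (condition == "cue") {
    u <- pmin(pmax((tt - cs) / (fs_time - cs), 0), 1)
    com_shift_mm * u^2 * (3 - 2 * u)        # smoothstep ramp over [CS, FS]
  } else rep(0, n)
  # tilt response: carried backward during the ramp, exponential recovery
  carry <- -55 * phi / max(phi_max, 1e-9)
  rec <- ifelse(tt > tilt_end, 1 - exp(-(tt - tilt_end) / 1.2), 0)
  tilt_resp <- carry * (1 - rec)
  x0 <- com_position(c(-0.11, 0.18), body = spec$body)
  x <- x0 + sway + drift + tilt_resp

  # map COM to an ankle-angle series (hip held), then render markers
  dxdth <- 1000 * (spec$body$link1_mass * spec$body$link1_com +
                   spec$body$link2_mass * spec$body$link1_length +
                   spec$body$link2_mass * spec$body$link2_com) /
           spec$body$total_mass                  # mm per rad near upright
  a1 <- -0.11 + (x0 - x) / dxdth                 # absolute ankle angle
  th_a <- a1 - phi
  th_h <- rep(0.18, n)
  markers <- render_markers(tt, th_a, th_h, phi, spec$body,
                            spec$marker_noise_sd,
                            seed = trial_seed(seed, 1, 881))

  # EMG envelopes (%MVC)
  gc <- 8 + ifelse(tt >= cs & tt <= fs_time, gc_slope * (tt - cs), 0) +
    ifelse(tt > fs_time, gc_slope * (fs_time - cs) *
             exp(-(tt - fs_time) / 2), 0) * (condition == "cue") +
    spec$gc_burst_amp *
      exp(-0.5 * ((tt - (fs_time + spec$gc_burst_latency_s)) / 0.025)^2)
  if (condition == "no_cue") gc <- 8 +
    spec$gc_burst_amp *
      exp(-0.5 * ((tt - (fs_time + spec$gc_burst_latency_s)) / 0.025)^2)
  ta <- 2 + 10 * exp(-0.5 * ((tt - (fs_time + 0.25)) / 0.06)^2)
  emg <- render_emg(tt, ta, gc, spec$emg_noise_sd,
                    seed = trial_seed(seed, 2, 882))

  events <- data.frame(
    name = c("cue_start", "cue_stop", "tilt_start", "tilt_stop"),
    t_s = c(if (condition == "cue") cs else NA_real_,
            if (condition == "cue") tilt_end else NA_real_,
            spec$tilt_time, tilt_end))
  truth <- list(condition = condition, delta_com = unname(
                  if (condition == "cue") com_shift_mm else 0),
                gc_slope = if (condition == "cue") gc_slope else 0,
                cs = cs, fs = fs_time, tilt_start = spec$tilt_time,
                tilt_stop = tilt_end,
                gc_burst_latency_s = spec$gc_burst_latency_s)
  list(markers = markers, emg = emg, events = events, truth = truth)
}

#' Recover cue-period metrics from a synthetic or recorded trial
#'
#' Applies the measurement pipeline: COM from markers via the segment
#' model, values at CS and FS for the displacement, and an OLS slope of
#' the GC envelope over the cue period.
#'
#' @param trial a [synth_trial()] record (or equivalent list of markers,
#'   emg, events).
#' @param seg a [segment_model()].
#' @param cs,fs window bounds (s); default from the trial events/truth.
#' @return data.frame row: delta_com_mm, slope_GC, com_cs, com_fs.
#' @export
recover_trial_metrics <- function(trial, seg = segment_model(),
                                  cs = trial$truth$cs,
                                  fs = trial$truth$fs) {
  com <- com_from_markers(trial$markers, seg)
  tt <- trial$markers$t_s
  i_cs <- which.min(abs(tt - cs))
  i_fs <- which.min(abs(tt - fs))
  win <- i_cs:i_fs
  sl <- unname(stats::coef(stats::lm.fit(cbind(1, tt[win] - cs),
                                         trial$emg$GC_env[win]))[2])
  data.frame(delta_com_mm = com[i_fs] - com[i_cs], slope_GC = sl,
             com_cs = com[i_cs], com_fs = com[i_fs])
}

#' Generate a synthetic multi-subject cohort and recover its metrics
#'
#' Per-subject effect sizes are drawn around the spec means
#' (between-subject SD `subject_sd_mm`), per-trial shifts around the
#' subject mean (`trial_sd_mm`, floored at zero). Returns the ground-truth
#' manifest together with recovered per-trial metrics, which is
#' sufficient to score any analysis without re-running generation.
#'
#' @param spec a [synth_spec()].
#' @param base_seed base seed; trials derive seeds via [trial_seed()].
#' @param conditions conditions to generate.
#' @param seg segment model used for recovery.
#' @param keep_records keep the full marker/EMG records (memory-heavy;
#'   default `FALSE`).
#' @return list with `manifest` (one row per trial: subject, condition,
#'   trial, stage, injected truth, recovered metrics) and, when requested,
#'   `records`.
#' @export
synth_cohort <- function(spec, base_seed = 1,
                         conditions = c("no_cue", "cue"),
                         seg = segment_model(), keep_records = FALSE) {
  rows <- list()
  records <- list()
  set.seed(as.integer(base_seed %% 2147483647))
  subj_shift <- pmax(stats::rnorm(spec$n_subjects, spec$com_shift_mm,
                                  spec$subject_sd_mm), 0)
  subj_slope <- if (spec$com_shift_mm > 0)
    pmax(spec$gc_slope * subj_shift / spec$com_shift_mm +
           stats::rnorm(spec$n_subjects, 0, 0.2), 0)
  else rep(spec$gc_slope, spec$n_subjects)
  k <- 0
  for (s in seq_len(spec$n_subjects)) {
    for (cond in conditions) {
      for (i in seq_len(spec$n_trials)) {
        k <- k + 1
        sd_trial <- trial_seed(base_seed, i,
                               stratum = s * 100 + match(cond, conditions))
        set.seed(trial_seed(sd_trial, 3, 883))   # effect-draw stream distinct from the trial's
        # a true null injects exactly zero: truncating jittered shifts at
        # zero would bias the cue condition positive
        shift_i <- if (spec$com_shift_mm > 0)
          max(subj_shift[s] + stats::rnorm(1, 0, spec$trial_sd_mm), 0)
        else 0
        tr <- synth_trial(spec, cond, seed = sd_trial,
                          com_shift_mm = shift_i,
                          gc_slope = subj_slope[s])
        met <- recover_trial_metrics(tr, seg)
        rows[[k]] <- cbind(
          data.frame(subject = s, condition = cond, trial = i,
                     stage = (i - 1) %/% 5 + 1,
                     true_delta_com = tr$truth$delta_com,
                     true_gc_slope = tr$truth$gc_slope,
                     cs = tr$truth$cs, fs = tr$truth$fs, seed = sd_trial),
          met)
        if (keep_records) records[[k]] <- tr
      }
    }
  }
  out <- list(manifest = do.call(rbind, rows), spec = spec,
              base_seed = base_seed)
  if (keep_records) out$records <- records
  out
}
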