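#' Write / read a 300-Hz marker table
#'
#' Headered CSV with `t_s` and `<marker>_x`, `<marker>_y` columns in mm.
#' Reading validates the schema and the sampling rate (300 Hz within
#' tolerance; small deviations are accepted with a warning).
#'
#' @param markers marker data.frame (see [com_from_markers()]).
#' @param path file path.
#' @return `read_markers` returns the validated data.frame.
#' @export
write_markers <- function(markers, path) {
  marker_cols(markers)
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @param expected_fs expected sampling rate (Hz).
#' @param fs_tol accepted relative deviation of the sampling rate.
#' @export
read_markers <- function(path, expected_fs = 300, fs_tol = 0.005) {
  d <- utils::read.csv(path)
  if (!"t_s" %in% names(d)) stop("marker file lacks the t_s column")
  marker_cols(d)
  check_rate(d$t_s, expected_fs, fs_tol, path)
  d
}

check_rate <- function(t_s, expected_fs, fs_tol, path) {
  dts <- diff(t_s)
  bad <- which(abs(dts - stats::median(dts)) > 0.25 * stats::median(dts))
  if (length(bad))
    stop(sprintf("irregular timestamps in %s (first bad index %d)",
                 path, bad[1]))
  fs <- 1 / stats::median(dts)
  if (abs(fs - expected_fs) / expected_fs > fs_tol)
    stop(sprintf("sampling rate %.2f Hz outside tolerance of %g Hz", fs,
                 expected_fs))
  if (abs(fs - expected_fs) > 1e-9)
    warning(sprintf("sampling rate %.3f Hz accepted (expected %g Hz)", fs,
                    expected_fs))
  invisible(fs)
}

#' Write / read an EMG table
#'
#' Headered CSV with `t_s`, raw `TA`/`GC` channels and, when present, the
#' `TA_env`/`GC_env` envelopes (%MVC). The MVC reference is carried in a
#' `# mvc:` comment line.
#'
#' @param emg EMG data.frame from [emg_from_sim()] or [synth_trial()].
#' @param path file path.
#' @export
write_emg <- function(emg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mvc: %.10g", attr(emg, "mvc") %||% 1), con)
  utils::write.csv(emg, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_emg
#' @param expected_fs expected sampling rate (Hz).
#' @param fs_tol accepted relative deviation of the sampling rate.
#' @export
read_emg <- function(path, expected_fs = 300, fs_tol = 0.005) {
  first <- readLines(path, n = 1)
  mvc <- 1
  skip <- 0
  if (startsWith(first, "# mvc:")) {
    mvc <- as.numeric(sub("# mvc:", "", first))
    skip <- 1
  }
  d <- utils::read.csv(path, skip = skip, comment.char = "")
  need <- c("t_s", "TA", "GC")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("EMG file lacks column(s): ",
                         paste(miss, collapse = ", "))
  check_rate(d$t_s, expected_fs, fs_tol, path)
  attr(d, "mvc") <- mvc
  d
}

#' Write / read an event table
#'
#' Two-column CSV `(name, t_s)`; missing times (e.g. no cue in the no-cue
#' condition) are stored as empty fields.
#'
#' @param events data.frame with `name`, `t_s`.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("name", "t_s") %in% names(events)))
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("name", "t_s") %in% names(d)))
    stop("event file must have columns name, t_s")
  d
}

#' Write / read a scenario as YAML
#'
#' Serialises every scalar field plus the floor trajectory, LLR block and
#' body parameters; angles in radians, COM in mm, times in seconds.
#'
#' @param scn a [scenario()].
#' @param path file path.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  x <- list(
    duration = scn$duration, dt = scn$dt,
    floor = list(tilt_start = scn$floor$tilt_start,
                 tilt_stop = scn$floor$tilt_stop,
                 max_angle_deg = scn$floor$max_angle_deg),
    preview = scn$preview, preview_enable_time = scn$preview_enable_time,
    cs_time = scn$cs_time, fs_time = scn$fs_time,
    x_ref = scn$x_ref, w_u = scn$w_u, w_du = scn$w_du,
    sigma_torque = scn$sigma_torque,
    noise_convention = scn$noise_convention,
    n_trials = scn$n_trials,
    llr = list(enabled = scn$llr$enabled,
               onset_offset = scn$llr$onset_offset,
               duration = scn$llr$duration, gc_level = scn$llr$gc_level,
               combine = scn$llr$combine),
    control_period = scn$control_period, dt_pred = scn$dt_pred,
    Np = scn$Np, Nm = scn$Nm, n_sub = scn$n_sub,
    sensory_delay = scn$sensory_delay, maxit = scn$maxit,
    body = unclass(scn$body),
    stiffness = list(k_ankle = scn$k_ankle, k_hip = scn$k_hip,
                     b_ankle = scn$b_ankle, b_hip = scn$b_hip),
    theta0 = scn$theta0)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  scenario(duration = x$duration, dt = x$dt,
           floor = floor_trajectory(x$floor$tilt_start, x$floor$tilt_stop,
                                    x$floor$max_angle_deg),
           preview = x$preview, preview_enable_time = x$preview_enable_time,
           cs_time = x$cs_time,
           x_ref = x$x_ref, w_u = x$w_u, w_du = x$w_du,
           sigma_torque = x$sigma_torque,
           noise_convention = x$noise_convention,
           n_trials = x$n_trials,
           llr = llr_config(x$llr$enabled, x$llr$onset_offset,
                            x$llr$duration, x$llr$gc_level, x$llr$combine),
           control_period = x$control_period, dt_pred = x$dt_pred,
           Np = x$Np, Nm = x$Nm, n_sub = x$n_sub,
           sensory_delay = x$sensory_delay, maxit = x$maxit,
           body = do.call(body_params, x$body),
           k_ankle = x$stiffness$k_ankle, k_hip = x$stiffness$k_hip,
           b_ankle = x$stiffness$b_ankle, b_hip = x$stiffness$b_hip,
           theta0 = as.numeric(x$theta0))
}

#' Export a trial trajectory as delimited text
#'
#' Columns: `t_s, phi_rad, theta_ankle_rad, theta_hip_rad, com_mm, a_TA,
#' a_GC, a_IL, a_GM`, one row per plant step (optionally decimated).
#'
#' @param tr a [run_trial()] result.
#' @param path file path.
#' @param every keep every `every`-th sample.
#' @export
write_trial <- function(tr, path, every = 1) {
  s <- tr$series[seq(1, nrow(tr$series), by = every), ]
  out <- data.frame(t_s = s$t, phi_rad = s$phi,
                    theta_ankle_rad = s$theta_ankle,
                    theta_hip_rad = s$theta_hip, com_mm = s$com_mm,
                    a_TA = s$a_TA, a_GC = s$a_GC, a_IL = s$a_IL,
                    a_GM = s$a_GM)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a statistics report as JSON
#'
#' @param results named list of `stat_result` objects or plain values.
#' @param path file path.
#' @export
write_stats_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
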