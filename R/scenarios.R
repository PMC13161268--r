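#' Simulation scenario
#'
#' Bundles all timings, model parameters, controller settings and the noise
#' specification for one simulated standing trial. Defaults reproduce the
#' baseline protocol: a 20-s trial at 1000 Hz with a 4-degree floor tilt
#' over 15-16 s, tilt preview (the simulation's cue) from 13 s, COM target
#' 61 mm, input weight 0.01, and 0.33 N m torque noise.
#'
#' @param duration trial length (s).
#' @param dt plant step (s).
#' @param floor a [floor_trajectory()].
#' @param preview logical; give the controller the scheduled tilt from
#'   `preview_enable_time` on (the no-cue condition sets this `FALSE`).
#' @param preview_enable_time,cs_time cue start CS (s); these must agree.
#' @param fs_time floor tilt start FS (s); must equal `floor$tilt_start`.
#' @param x_ref COM target (mm).
#' @param w_u,w_du MPC input and input-change weights.
#' @param sigma_torque joint torque noise SD (N m).
#' @param noise_convention see [noise_spec()].
#' @param n_trials default cohort size.
#' @param llr an [llr_config()].
#' @param control_period,dt_pred,Np,Nm,n_sub,sensory_delay,maxit see
#'   [mpc_config()].
#' @param body a [body_params()].
#' @param muscles four [muscle_params()] (TA, GC, IL, GM).
#' @param k_ankle,k_hip,b_ankle,b_hip stiffness gains, see
#'   [stiffness_params()].
#' @param theta0 initial posture `c(ankle, hip)` (rad); `NULL` solves the
#'   ankle angle so the initial COM equals `x_ref` (hip fixed at 0.18 rad),
#'   matching the convention that target and initial COM coincide.
#' @return an object of class `scenario`.
#' @export
scenario <- function(duration = 20, dt = 1e-3,
                     floor = floor_trajectory(15, 16, 4),
                     preview = TRUE, preview_enable_time = 13, cs_time = 13,
                     fs_time = floor$tilt_start,
                     x_ref = 61, w_u = 0.01, w_du = 1,
                     sigma_torque = 0.33,
                     noise_convention = "sqrt_dt",
                     n_trials = 20, llr = llr_config(FALSE),
                     control_period = 0.1, dt_pred = 0.1, Np = 30, Nm = 2,
                     n_sub = 10,
                     sensory_delay = 0.15, maxit = 40,
                     body = body_params(), muscles = default_muscles(),
                     k_ankle = 250, k_hip = 150, b_ankle = 80, b_hip = 40,
                     theta0 = NULL) {
  stopifnot(cs_time <= fs_time, fs_time == floor$tilt_start,
            floor$tilt_stop <= duration,
            preview_enable_time == cs_time)
  if (is.null(theta0)) {
    theta0 <- if (x_ref == 61) c(-0.11, 0.18)
              else initial_posture_for_target(x_ref, body)
  }
  structure(list(duration = duration, dt = dt, floor = floor,
                 preview = preview, preview_enable_time = preview_enable_time,
                 cs_time = cs_time, fs_time = fs_time,
                 x_ref = x_ref, w_u = w_u, w_du = w_du,
                 sigma_torque = sigma_torque,
                 noise_convention = noise_convention,
                 n_trials = n_trials, llr = llr,
                 control_period = control_period, dt_pred = dt_pred,
                 Np = Np, Nm = Nm,
                 n_sub = n_sub, sensory_delay = sensory_delay, maxit = maxit,
                 body = body, muscles = muscles,
                 k_ankle = k_ankle, k_hip = k_hip,
                 b_ankle = b_ankle, b_hip = b_hip,
                 theta0 = theta0),
            class = "scenario")
}

#' Initial posture matching a COM target
#'
#' One-dimensional inverse kinematics: the hip is held at its baseline
#' value and the ankle angle is solved so that the standing COM equals the
#' requested target. If no ankle angle in the physiological range works,
#' both joints are adjusted by a least-norm search.
#'
#' @param x_ref_mm COM target (mm anterior of the ankle).
#' @param body a [body_params()].
#' @param hip hip angle held fixed (rad).
#' @return numeric `c(theta_ankle, theta_hip)` with
#'   `com_position(theta) == x_ref_mm` to < 0.5 mm.
#' @export
initial_posture_for_target <- function(x_ref_mm, body = body_params(),
                                       hip = 0.18) {
  f <- function(a) com_position(c(a, hip), body = body) - x_ref_mm
  root <- tryCatch(stats::uniroot(f, c(-0.8, 0.6), tol = 1e-10),
                   error = function(e) NULL)
  if (!is.null(root)) return(c(root$root, hip))
  # least-norm fallback: move both joints from the baseline posture
  obj <- function(th) (com_position(th, body = body) - x_ref_mm)^2 +
    1e-6 * sum((th - c(-0.11, 0.18))^2)
  stats::optim(c(-0.11, 0.18), obj)$par
}

mpc_config_from_scenario <- function(scn) {
  mpc_config(Np = scn$Np, Nm = scn$Nm, dt_pred = scn$dt_pred,
             control_period = scn$control_period, x_ref = scn$x_ref,
             w_u = scn$w_u, w_du = scn$w_du,
             sensory_delay = scn$sensory_delay,
             preview_enable_time = scn$preview_enable_time,
             n_sub = scn$n_sub, maxit = scn$maxit)
}

model_from_scenario <- function(scn) {
  stiff <- stiffness_params(k_ankle = scn$k_ankle, k_hip = scn$k_hip,
                            b_ankle = scn$b_ankle, b_hip = scn$b_hip,
                            eq_ankle = scn$theta0[1], eq_hip = scn$theta0[2])
  model_pack(body = scn$body, muscles = scn$muscles, stiffness = stiff,
             floor = scn$floor, th_ref = scn$theta0)
}

#' Run one closed-loop trial
#'
#' Plant at 1000 Hz (Euler-Maruyama with additive joint-torque noise), MPC
#' re-optimisation every `control_period` with the command held between
#' ticks, passive stiffness, delay compensation through the internal model,
#' and the optional LLR window. A fall (divergence) is a reportable
#' outcome: the result is truncated at the failure time with `fell = TRUE`.
#'
#' @param scn a [scenario()].
#' @param seed integer seed; `(scenario, seed)` fully determines the
#'   trajectory.
#' @return an object of class `trial_result`: `series` (1000-Hz data.frame
#'   with t, phi, angles, velocities, COM in mm, four activations),
#'   `commands` (per-tick data.frame with the three MPC channels and solver
#'   diagnostics), `scenario`, `seed`, `fell`, `fail_time`.
#' @export
run_trial <- function(scn, seed = 1) {
  stopifnot(inherits(scn, "scenario"))
  cfg <- mpc_config_from_scenario(scn)
  model <- model_from_scenario(scn)
  dt <- scn$dt
  n_steps <- round(scn$duration / dt)
  spt <- round(scn$control_period / dt)        # plant steps per tick
  n_ticks <- n_steps %/% spt
  delay_steps <- round(scn$sensory_delay / dt)

  set.seed(as.integer(seed %% 2147483647))
  sd_step <- if (scn$noise_convention == "sqrt_dt")
    scn$sigma_torque / sqrt(dt) else scn$sigma_torque
  noise <- matrix(stats::rnorm(2 * n_steps, sd = sd_step), n_steps, 2)

  states <- matrix(NA_real_, n_steps + 1, 5)   # t th_a th_h om_a om_h
  acts <- matrix(0, n_steps + 1, 4)
  applied <- matrix(0, n_steps, 4)             # per-step command log
  states[1, ] <- c(0, scn$theta0[1], scn$theta0[2], 0, 0)
  diag_rows <- vector("list", n_ticks)
  u_prev <- c(0, 0, 0)
  moves_prev <- NULL
  fell <- FALSE
  fail_time <- NA_real_
  last_filled <- 1L

  for (j in seq_len(n_ticks)) {
    t0 <- (j - 1) * scn$control_period
    idx <- (j - 1L) * spt                      # current plant step count
    # -- delay compensation: roll the (exactly known) past state forward
    meas_idx <- max(0L, idx - delay_steps)
    est <- states[meas_idx + 1L, 2:5]
    if (idx > meas_idx) {
      hist <- applied[(meas_idx + 1L):idx, , drop = FALSE]
      est <- cpp_rollout_logged(est, hist, meas_idx * dt, dt, model)
    }
    preview_on <- isTRUE(scn$preview) && t0 >= scn$preview_enable_time
    phi_hold <- cpp_floor_angle(t0, scn$floor$tilt_start,
                                scn$floor$tilt_stop, scn$floor$max_angle)[1]
    warm <- if (is.null(moves_prev)) NULL
            else c(moves_prev[-(1:3)], moves_prev[(3 * scn$Nm - 2):(3 * scn$Nm)])
    cmd <- solve_step(est, u_prev, cfg, model, t0 = t0, preview = preview_on,
                      phi_hold = phi_hold, warm_start = warm)
    cmd <- apply_llr(cmd, t0, scn$floor$tilt_start, scn$llr)
    diag_rows[[j]] <- c(t0, cmd$u, cmd$cost, as.numeric(cmd$converged))
    moves_prev <- cmd$moves
    u_prev <- cmd$u

    rows <- (idx + 1L):(idx + spt)
    seg <- cpp_plant_advance(states[idx + 1L, 2:5], acts[idx + 1L, ],
                             cmd$activations, t0, dt, spt,
                             noise[rows, , drop = FALSE], model)
    states[rows + 1L, ] <- seg[, 1:5]
    acts[rows + 1L, ] <- seg[, 6:9]
    applied[rows, ] <- matrix(cmd$activations, spt, 4, byrow = TRUE)
    if (anyNA(seg[, 2]) || max(abs(seg[, 2:3]), na.rm = TRUE) > 1.2) {
      fell <- TRUE
      bad <- which(is.na(seg[, 2]) | abs(seg[, 2]) > 1.2 | abs(seg[, 3]) > 1.2)[1]
      fail_time <- seg[max(bad - 1, 1), 1]
      last_filled <- idx + 1L + ifelse(is.na(seg[bad, 2]), bad - 1L, bad)
      break
    }
    last_filled <- idx + spt + 1L
  }

  keep <- seq_len(last_filled)
  phi <- cpp_floor_angle_vec(states[keep, 1], scn$floor$tilt_start,
                             scn$floor$tilt_stop, scn$floor$max_angle)
  com <- vapply(keep, function(i)
    cpp_com(states[i, 2:3], phi[i], model), numeric(1)) * 1000
  series <- data.frame(t = states[keep, 1],
                       phi = phi,
                       theta_ankle = states[keep, 2],
                       theta_hip = states[keep, 3],
                       omega_ankle = states[keep, 4],
                       omega_hip = states[keep, 5],
                       com_mm = com,
                       a_TA = acts[keep, 1], a_GC = acts[keep, 2],
                       a_IL = acts[keep, 3], a_GM = acts[keep, 4])
  dg <- do.call(rbind, diag_rows[!vapply(diag_rows, is.null, logical(1))])
  commands <- data.frame(t = dg[, 1], u_TA = dg[, 2], u_GC = dg[, 3],
                         u_hip = dg[, 4], cost = dg[, 5],
                         converged = dg[, 6] > 0)
  structure(list(series = series, commands = commands, scenario = scn,
                 seed = seed, fell = fell, fail_time = fail_time),
            class = "trial_result")
}

# vectorised floor angle (positions only)
cpp_floor_angle_vec <- function(t, ts, te, mx) {
  if (mx <= 0) return(rep(0, length(t)))
  rate <- mx / (te - ts)
  pmin(pmax((t - ts) * rate, 0), mx)
}

#' Deterministic per-trial seed derivation
#'
#' Counter-based mix of the base seed, an optional stratum (sweep grid
#' index) and the trial index, passed through Park-Miller iterations so
#' that structured inputs (consecutive trials, neighbouring strata) give
#' unrelated generator states; linearly related seed values fed directly
#' to `set.seed` produce visibly correlated first draws. Always below
#' 2^31.
#'
#' @param base_seed integer base seed.
#' @param i trial index (1-based).
#' @param stratum sweep grid index (0 for plain cohorts).
#' @return integer seed.
#' @export
trial_seed <- function(base_seed, i, stratum = 0) {
  pm <- function(x) {                  # exact in doubles: 16807 * m < 2^53
    for (k in 1:5) x <- (16807 * x) %% 2147483647
    x
  }
  x <- (abs(as.numeric(base_seed)) %% 2147483645) + 1
  x <- pm(x)
  x <- pm((x + (abs(stratum) %% 1e5) * 2654435 + 1) %% 2147483646 + 1)
  x <- pm((x + abs(i) * 7919 + 13) %% 2147483646 + 1)
  as.integer(x)
}

#' Run a cohort of independent trials
#'
#' @param scn a [scenario()].
#' @param n number of trials (default `scn$n_trials`, 20).
#' @param base_seed base seed; per-trial seeds come from [trial_seed()].
#' @param stratum sweep grid index forwarded to [trial_seed()].
#' @return list of [run_trial()] results.
#' @export
run_cohort <- function(scn, n = scn$n_trials, base_seed = 1, stratum = 0) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i)
    run_trial(scn, trial_seed(base_seed, i, stratum)))
}

#' Cue-period (CS-FS) metrics of one trial
#'
#' Differences of COM and joint angles between the tilt-start (FS) and
#' cue-start (CS) samples, and ordinary-least-squares slopes of the TA and
#' GC activity (in % of maximum, so slopes are in percent/s) over the
#' cue period.
#'
#' @param tr a [run_trial()] result (or any list with a `series`
#'   data.frame containing t, com_mm, theta_ankle, theta_hip, a_TA, a_GC).
#' @param cs,fs cue start and tilt start (s); defaults from the scenario.
#' @return an object of class `cue_metrics`: `delta_com` (mm), `delta_hip`,
#'   `delta_ankle` (rad), `slope_TA`, `slope_GC` (%/s), values at CS and
#'   FS, and `mean_u2` (time-averaged sum of squared activations).
#' @export
cue_metrics <- function(tr, cs = tr$scenario$cs_time, fs = tr$scenario$fs_time) {
  s <- tr$series
  stopifnot(cs < fs, fs <= max(s$t))
  i_cs <- which.min(abs(s$t - cs))
  i_fs <- which.min(abs(s$t - fs))
  win <- i_cs:i_fs
  if (length(win) < 2) stop("cue window too short for a slope")
  tt <- s$t[win] - cs
  slope <- function(y) unname(stats::coef(stats::lm.fit(cbind(1, tt), y))[2])
  structure(list(
    delta_com = s$com_mm[i_fs] - s$com_mm[i_cs],
    delta_hip = s$theta_hip[i_fs] - s$theta_hip[i_cs],
    delta_ankle = s$theta_ankle[i_fs] - s$theta_ankle[i_cs],
    slope_TA = slope(100 * s$a_TA[win]),
    slope_GC = slope(100 * s$a_GC[win]),
    com_cs = s$com_mm[i_cs], com_fs = s$com_mm[i_fs],
    ankle_cs = s$theta_ankle[i_cs], ankle_fs = s$theta_ankle[i_fs],
    hip_cs = s$theta_hip[i_cs], hip_fs = s$theta_hip[i_fs],
    mean_u2 = mean(s$a_TA^2 + s$a_GC^2 + s$a_IL^2 + s$a_GM^2)
  ), class = "cue_metrics")
}

cohort_metrics <- function(trials, sweep_value = NA_real_) {
  rows <- lapply(seq_along(trials), function(i) {
    m <- cue_metrics(trials[[i]])
    data.frame(sweep_value = sweep_value, trial = i,
               delta_com_mm = m$delta_com, delta_hip_rad = m$delta_hip,
               delta_ankle_rad = m$delta_ankle,
               slope_TA = m$slope_TA, slope_GC = m$slope_GC,
               mean_u2 = m$mean_u2, fell = trials[[i]]$fell)
  })
  do.call(rbind, rows)
}

#' Input-weight sweep
#'
#' Re-runs the base scenario over a log-spaced grid of MPC input weights
#' (paper grid: 20 values from 0.001 to 0.1) and summarises the cue-period
#' metrics per trial.
#'
#' @param base a [scenario()].
#' @param w_values input-weight grid.
#' @param n_trials trials per grid point.
#' @param base_seed base seed (fresh seeds per grid point).
#' @return data.frame with one row per (w_u, trial): sweep_value, trial,
#'   delta_com_mm, delta_hip_rad, delta_ankle_rad, slope_TA, slope_GC,
#'   mean_u2, fell.
#' @export
sweep_weights <- function(base = scenario(),
                          w_values = exp(seq(log(0.001), log(0.1),
                                             length.out = 20)),
                          n_trials = base$n_trials, base_seed = 1) {
  out <- lapply(seq_along(w_values), function(k) {
    scn <- base
    scn$w_u <- w_values[k]
    cohort_metrics(run_cohort(scn, n_trials, base_seed, stratum = k),
                   sweep_value = w_values[k])
  })
  do.call(rbind, out)
}

#' COM-target sweep
#'
#' Varies the COM target (paper grid: -50 to +100 mm in 10-mm steps); for
#' each target the initial posture is re-solved so that the initial COM
#' equals the target, and the stiffness equilibrium and muscle reference
#' posture follow the initial posture.
#'
#' @inheritParams sweep_weights
#' @param targets COM-target grid (mm).
#' @return data.frame as in [sweep_weights()] with `sweep_value` = target.
#' @export
sweep_targets <- function(base = scenario(), targets = seq(-50, 100, by = 10),
                          n_trials = base$n_trials, base_seed = 1) {
  out <- lapply(seq_along(targets), function(k) {
    scn <- base
    scn$x_ref <- targets[k]
    scn$theta0 <- initial_posture_for_target(targets[k], scn$body)
    cohort_metrics(run_cohort(scn, n_trials, base_seed, stratum = k),
                   sweep_value = targets[k])
  })
  do.call(rbind, out)
}

#' Tilt-magnitude sweep
#'
#' Varies the maximum floor tilt (paper grid: 1-8 degrees) at a fixed 1-s
#' ramp duration, so the tilt rate scales with the magnitude.
#'
#' @inheritParams sweep_weights
#' @param tilts_deg tilt grid (degrees).
#' @return data.frame as in [sweep_weights()] with `sweep_value` = tilt.
#' @export
sweep_tilts <- function(base = scenario(), tilts_deg = 1:8,
                        n_trials = base$n_trials, base_seed = 1) {
  out <- lapply(seq_along(tilts_deg), function(k) {
    scn <- base
    scn$floor <- floor_trajectory(base$floor$tilt_start, base$floor$tilt_stop,
                                  tilts_deg[k])
    cohort_metrics(run_cohort(scn, n_trials, base_seed, stratum = k),
                   sweep_value = tilts_deg[k])
  })
  do.call(rbind, out)
}
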