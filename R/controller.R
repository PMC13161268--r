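#' Model predictive control configuration
#'
#' Defaults follow the baseline controller: a 3-s prediction horizon of 30
#' steps (0.1 s per step), a 2-step control horizon with the last move held
#' to the horizon end, re-optimisation every prediction step, COM target
#' 61 mm, input weight 0.01, input-change weight 1, and a 150-ms sensory
#' delay compensated through the internal model.
#'
#' @param Np prediction horizon (steps).
#' @param Nm control horizon (steps), `1 <= Nm <= Np`.
#' @param dt_pred prediction step (s).
#' @param control_period time between re-optimisations (s).
#' @param x_ref COM target (mm anterior of the ankle).
#' @param w_u input weight.
#' @param w_du input-change weight.
#' @param sensory_delay sensory delay (s).
#' @param preview_enable_time time (s) from which the scheduled tilt is known
#'   to the internal model; `Inf` disables preview.
#' @param n_sub internal-model Euler sub-steps per prediction step.
#' @param maxit iteration cap of the per-tick solver.
#' @return an object of class `mpc_config`.
#' @export
mpc_config <- function(Np = 30, Nm = 2, dt_pred = 0.1, control_period = 0.1,
                       x_ref = 61, w_u = 0.01, w_du = 1,
                       sensory_delay = 0.15, preview_enable_time = 13,
                       n_sub = 10, maxit = 40) {
  stopifnot(Np >= Nm, Nm >= 1, dt_pred > 0, control_period > 0,
            w_u >= 0, w_du >= 0, sensory_delay >= 0, n_sub >= 1)
  structure(list(Np = as.integer(Np), Nm = as.integer(Nm), dt_pred = dt_pred,
                 control_period = control_period, x_ref = x_ref,
                 w_u = w_u, w_du = w_du, sensory_delay = sensory_delay,
                 preview_enable_time = preview_enable_time,
                 n_sub = as.integer(n_sub), maxit = as.integer(maxit),
                 bounds_lower = c(0, 0, -1), bounds_upper = c(1, 1, 1)),
            class = "mpc_config")
}

#' Long-latency-reflex (LLR) extension configuration
#'
#' A constant GC activation applied during a fixed window after tilt onset,
#' on top of (or overriding) the MPC command.
#'
#' @param enabled logical.
#' @param onset_offset window start after tilt onset (s).
#' @param duration window length (s).
#' @param gc_level GC activation level in `[0, 1]`.
#' @param combine "add" (add then clip to `[0, 1]`, default) or "override".
#' @return an object of class `llr_config`.
#' @export
llr_config <- function(enabled = FALSE, onset_offset = 0.100,
                       duration = 0.100, gc_level = 0.5,
                       combine = c("add", "override")) {
  stopifnot(gc_level >= 0, gc_level <= 1, duration > 0, onset_offset >= 0)
  structure(list(enabled = enabled, onset_offset = onset_offset,
                 duration = duration, gc_level = gc_level,
                 combine = match.arg(combine)),
            class = "llr_config")
}

#' Passive stiffness torque (PD on relative joint angles)
#'
#' @param state a [plant_state()].
#' @param p a [stiffness_params()].
#' @return numeric `c(tau_ankle, tau_hip)` (N m).
#' @export
stiffness_torque <- function(state, p = stiffness_params()) {
  stopifnot(inherits(p, "stiffness_params"))
  c(tau_ankle = -p$k_ankle * (state$theta_ankle - p$eq_ankle)
      - p$b_ankle * state$omega_ankle,
    tau_hip = -p$k_hip * (state$theta_hip - p$eq_hip)
      - p$b_hip * state$omega_hip)
}

#' Resolve the signed hip channel into IL/GM activations
#'
#' Positive input drives only the hip flexor IL, negative only the extensor
#' GM; they are never co-active. Out-of-bounds input is clipped with a
#' warning.
#'
#' @param u_hip signed hip command in `[-1, 1]`.
#' @return numeric `c(a_IL, a_GM)`.
#' @export
resolve_hip <- function(u_hip) {
  if (u_hip < -1 || u_hip > 1) {
    warning("hip command out of [-1, 1]; clipped")
    u_hip <- min(max(u_hip, -1), 1)
  }
  c(a_IL = max(u_hip, 0), a_GM = max(-u_hip, 0))
}

#' Resolve a 3-channel command into the four muscle activations
#' @param u numeric `c(u_TA, u_GC, u_hip)`.
#' @return numeric `c(TA, GC, IL, GM)`.
#' @export
resolve_command <- function(u) {
  hip <- resolve_hip(u[3])
  c(TA = min(max(u[1], 0), 1), GC = min(max(u[2], 0), 1),
    IL = unname(hip[1]), GM = unname(hip[2]))
}

#' Noise-free rollout of the internal model over the prediction horizon
#'
#' The Nm control moves are applied one per prediction step; the last move
#' is held to the horizon end (move blocking). With preview the scheduled
#' floor trajectory is used, otherwise the floor is frozen at `phi_hold`.
#'
#' @param moves numeric vector of length `3 * Nm` (TA, GC, hip per move).
#' @param state0 a [plant_state()] (or numeric `c(th_a, th_h, om_a, om_h)`).
#' @param t0 current time (s).
#' @param cfg an [mpc_config()].
#' @param model a [model_pack()] list.
#' @param preview logical; is the scheduled tilt known?
#' @param phi_hold floor angle (rad) assumed constant when `preview = FALSE`.
#' @return data.frame with Np rows: `t`, `theta_ankle`, `theta_hip`,
#'   `omega_ankle`, `omega_hip`, `com_mm`. Rows are `NA` past a divergence.
#' @export
mpc_predict <- function(moves, state0, t0, cfg = mpc_config(),
                        model = model_pack(), preview = TRUE, phi_hold = 0) {
  stopifnot(length(moves) == 3 * cfg$Nm)
  est <- if (inherits(state0, "plant_state")) as_state_vec(state0) else state0
  out <- cpp_predict_traj(moves, est, t0, model, cfg$Np, cfg$Nm, cfg$dt_pred,
                          cfg$n_sub, preview, phi_hold)
  data.frame(t = out[, 1], theta_ankle = out[, 2], theta_hip = out[, 3],
             omega_ankle = out[, 4], omega_hip = out[, 5],
             com_mm = out[, 6] * 1000)
}

#' MPC stage cost over a predicted horizon
#'
#' `J = sum_k (x_COM,k - x_ref)^2 + sum_c (w_u u_k,c)^2 + (w_du du_k,c)^2`
#' with COM error in metres, inputs per step after move blocking, and the
#' first input change differenced against the last applied command.
#'
#' @param com_mm predicted COM sequence (mm), length Np.
#' @param inputs Np x 3 matrix of applied inputs per prediction step.
#' @param u_prev last applied command (length 3).
#' @param cfg an [mpc_config()].
#' @return scalar cost `J >= 0`.
#' @export
mpc_cost <- function(com_mm, inputs, u_prev, cfg = mpc_config()) {
  inputs <- matrix(inputs, ncol = 3)
  if (length(com_mm) != nrow(inputs))
    stop("COM sequence and input sequence lengths differ")
  err <- (com_mm - cfg$x_ref) / 1000
  du <- diff(rbind(matrix(u_prev, 1, 3), inputs))
  sum(err^2) + sum((cfg$w_u * inputs)^2) + sum((cfg$w_du * du)^2)
}

#' Compensate the sensory delay through the internal model
#'
#' Rolls the delayed measurement forward under the logged applied commands
#' with the noise-free internal model. With a noise-free plant the estimate
#' equals the true current state to integration tolerance. If the history
#' does not cover the delay (warm-up), the delayed state is returned as a
#' zero-order hold with a warning.
#'
#' @param delayed_state state at `t - delay`: a [plant_state()] or numeric
#'   `c(th_a, th_h, om_a, om_h)`.
#' @param history matrix of per-plant-step applied activations (rows
#'   covering `[t - delay, t)`, columns TA, GC, IL, GM); `NULL` or too few
#'   rows triggers the zero-order-hold fallback.
#' @param delay delay span (s).
#' @param t current time (s).
#' @param dt plant step (s).
#' @param model a [model_pack()] list.
#' @return numeric state estimate `c(th_a, th_h, om_a, om_h)` at `t`.
#' @export
compensate_delay <- function(delayed_state, history, delay, t, dt = 1e-3,
                             model = model_pack()) {
  est <- if (inherits(delayed_state, "plant_state"))
    as_state_vec(delayed_state) else as.numeric(delayed_state)
  if (delay <= 0) return(est)
  n <- round(delay / dt)
  if (is.null(history) || nrow(history) < n) {
    warning("input history does not cover the sensory delay; using delayed state")
    return(est)
  }
  hist <- history[seq_len(n) + (nrow(history) - n), , drop = FALSE]
  cpp_rollout_logged(est, hist, t - delay, dt, model)
}

#' Solve one MPC tick
#'
#' Minimises [mpc_cost()] over the `3 * Nm` decision vector under box
#' bounds (TA, GC in `[0, 1]`, hip in `[-1, 1]`) with L-BFGS-B, warm-started
#' from the shifted previous solution. The all-zeros sequence and the
#' repeated previous command are always evaluated as candidate points, so
#' the returned cost never exceeds either.
#'
#' @param estimate current state estimate (numeric 4-vector or
#'   [plant_state()]).
#' @param u_prev last applied command (length 3).
#' @param cfg an [mpc_config()].
#' @param model a [model_pack()] list.
#' @param t0 current time (s).
#' @param preview logical; scheduled tilt known to the internal model.
#' @param phi_hold floor angle held constant when `preview = FALSE`.
#' @param warm_start optional full previous solution (length `3 * Nm`) to
#'   shift; defaults to repeating `u_prev`.
#' @return a `control_command` list: `u` (first move, length 3),
#'   `activations` (resolved 4-vector), `moves` (full solution), `cost`,
#'   `converged`, `counts`.
#' @export
solve_step <- function(estimate, u_prev, cfg = mpc_config(),
                       model = model_pack(), t0 = 0, preview = FALSE,
                       phi_hold = 0, warm_start = NULL) {
  est <- if (inherits(estimate, "plant_state")) as_state_vec(estimate)
         else as.numeric(estimate)
  stopifnot(all(is.finite(est)), length(u_prev) == 3)
  Nm <- cfg$Nm
  lower <- rep(cfg$bounds_lower, Nm)
  upper <- rep(cfg$bounds_upper, Nm)
  xref_m <- cfg$x_ref / 1000
  fn <- function(u) cpp_mpc_cost(u, est, u_prev, t0, model, cfg$Np, Nm,
                                 cfg$dt_pred, cfg$n_sub, cfg$w_u, cfg$w_du,
                                 xref_m, preview, phi_hold)
  gr <- function(u) cpp_mpc_grad(u, est, u_prev, t0, model, cfg$Np, Nm,
                                 cfg$dt_pred, cfg$n_sub, cfg$w_u, cfg$w_du,
                                 xref_m, preview, phi_hold, 1e-5)
  if (is.null(warm_start)) warm_start <- rep(u_prev, Nm)
  # shift is done by the caller; candidates guard the optimality lower bound
  cand <- list(warm = pmin(pmax(warm_start, lower), upper),
               zeros = rep(0, 3 * Nm),
               prev = rep(u_prev, Nm))
  cand_cost <- vapply(cand, fn, numeric(1))
  start <- cand[[which.min(cand_cost)]]
  opt <- tryCatch(
    stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = cfg$maxit)),
    error = function(e) list(par = start, value = fn(start),
                             convergence = 51L, counts = c(NA, NA)))
  best <- if (opt$value <= min(cand_cost)) list(par = opt$par, value = opt$value)
          else list(par = cand[[which.min(cand_cost)]], value = min(cand_cost))
  u1 <- best$par[1:3]
  structure(list(u = u1, activations = resolve_command(u1),
                 moves = best$par, cost = best$value,
                 converged = identical(opt$convergence, 0L),
                 counts = opt$counts),
            class = "control_command")
}

#' Apply the long-latency-reflex window to a command
#'
#' Inside `[tilt_onset + onset_offset, tilt_onset + onset_offset + duration)`
#' the GC activation is combined with `gc_level` (added then clipped to
#' `[0, 1]`, or overridden); the command is unchanged outside the window.
#'
#' @param command a `control_command` (or any list with an `activations`
#'   4-vector and `u` 3-vector).
#' @param t current time (s).
#' @param tilt_onset tilt onset time (s).
#' @param cfg an [llr_config()].
#' @return the (possibly modified) command.
#' @export
apply_llr <- function(command, t, tilt_onset, cfg = llr_config(enabled = TRUE)) {
  if (!isTRUE(cfg$enabled)) return(command)
  w0 <- tilt_onset + cfg$onset_offset
  if (t < w0 || t >= w0 + cfg$duration) return(command)
  gc <- command$activations[2]
  gc <- if (cfg$combine == "add") min(gc + cfg$gc_level, 1) else cfg$gc_level
  command$activations[2] <- gc
  command$u[2] <- gc
  command
}
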