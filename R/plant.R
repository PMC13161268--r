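#' Floor angle, velocity and acceleration at a time point
#'
#' The floor follows a constant-rate ramp from zero to the maximum tilt,
#' clamped outside the ramp window. Angular acceleration is reported as 0
#' (the velocity discontinuities at the ramp endpoints are absorbed by the
#' integrator step).
#'
#' @param t time (s), scalar or vector.
#' @param traj a [floor_trajectory()].
#' @return data.frame with columns `phi` (rad), `phi_dot` (rad/s),
#'   `phi_ddot` (rad/s^2).
#' @export
floor_angle <- function(t, traj) {
  stopifnot(inherits(traj, "floor_trajectory"), all(is.finite(t)))
  out <- t(vapply(t, cpp_floor_angle, numeric(3),
                  tilt_start = traj$tilt_start, tilt_stop = traj$tilt_stop,
                  tilt_max = traj$max_angle))
  data.frame(phi = out[, 1], phi_dot = out[, 2], phi_ddot = out[, 3])
}

#' Plant state constructor
#'
#' @param theta_ankle ankle angle (rad), shank relative to the floor normal;
#'   negative is anterior lean.
#' @param theta_hip hip angle (rad), HAT relative to shank; positive is
#'   posterior lean.
#' @param omega_ankle,omega_hip joint angular velocities (rad/s).
#' @param t time (s).
#' @param activations 4-vector of muscle activations in `[0, 1]`
#'   (TA, GC, IL, GM).
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(theta_ankle = -0.11, theta_hip = 0.18,
                        omega_ankle = 0, omega_hip = 0, t = 0,
                        activations = c(0, 0, 0, 0)) {
  vals <- c(theta_ankle, theta_hip, omega_ankle, omega_hip, t, activations)
  stopifnot(all(is.finite(vals)), length(activations) == 4,
            all(activations >= 0), all(activations <= 1))
  structure(list(t = t, theta_ankle = theta_ankle, theta_hip = theta_hip,
                 omega_ankle = omega_ankle, omega_hip = omega_hip,
                 activations = as.numeric(activations)),
            class = "plant_state")
}

as_state_vec <- function(state) {
  c(state$theta_ankle, state$theta_hip, state$omega_ankle, state$omega_hip)
}

#' Hill-type muscle force
#'
#' Active force is `a * f_max * fL(l) * fV(v)` with a Gaussian force-length
#' curve and a hyperbolic force-velocity curve (eccentric plateau at 1.8
#' f_max, slope-matched at v = 0); the passive element is exponential in
#' stretch beyond its slack length. The returned force is never negative.
#'
#' @param a activation in `[0, 1]`.
#' @param l muscle length (m), must be positive.
#' @param v lengthening velocity (m/s); negative while shortening.
#' @param p a [muscle_params()].
#' @return force (N).
#' @export
muscle_force <- function(a, l, v, p) {
  stopifnot(inherits(p, "muscle_params"), a >= 0, a <= 1)
  if (l <= 0) stop("invalid muscle geometry: nonpositive length")
  model <- model_pack(muscles = replace_muscle(default_muscles(), p))
  cpp_muscle_force(a, l, v, muscle_index(p$name) - 1L, model)
}

muscle_index <- function(name) match(name, c("TA", "GC", "IL", "GM"))

replace_muscle <- function(muscles, p) {
  muscles[[p$name]] <- p
  muscles
}

#' Muscle length and velocity from the joint state
#'
#' Constant-moment-arm map, linear in the joint angle:
#' `l = l_opt - sign * r * (theta - theta_ref)` and `v = -sign * r * omega`,
#' so a muscle shortens while the joint rotates in its pulling direction.
#'
#' @param state a [plant_state()].
#' @param p a [muscle_params()].
#' @param th_ref reference posture `c(ankle, hip)` (rad) at which the muscle
#'   is at optimal length.
#' @return list with elements `l` (m) and `v` (m/s).
#' @export
muscle_kinematics <- function(state, p, th_ref = c(-0.11, 0.18)) {
  stopifnot(inherits(state, "plant_state"), inherits(p, "muscle_params"))
  model <- model_pack(muscles = replace_muscle(default_muscles(), p),
                      th_ref = th_ref)
  lv <- cpp_muscle_geom(c(state$theta_ankle, state$theta_hip),
                        c(state$omega_ankle, state$omega_hip),
                        muscle_index(p$name) - 1L, model)
  list(l = lv[1], v = lv[2])
}

#' Net joint torques from muscles, stiffness and noise
#'
#' @param state a [plant_state()].
#' @param activations 4-vector (TA, GC, IL, GM) in `[0, 1]`.
#' @param model a [model_pack()] list.
#' @param noise per-joint additive torque `c(ankle, hip)` (N m).
#' @param stiffness include the passive PD stiffness contribution.
#' @return named numeric `c(tau_ankle, tau_hip)` (N m).
#' @export
joint_torques <- function(state, activations, model = model_pack(),
                          noise = c(0, 0), stiffness = TRUE) {
  stopifnot(all(activations >= 0), all(activations <= 1),
            length(activations) == 4)
  tau <- cpp_joint_torques(c(state$theta_ankle, state$theta_hip),
                           c(state$omega_ankle, state$omega_hip),
                           activations, model, noise, stiffness)
  c(tau_ankle = tau[1], tau_hip = tau[2])
}

#' Joint accelerations of the two-link body on the tilting floor
#'
#' Solves the two-link Lagrangian with prescribed base rotation: gravity is
#' evaluated on the absolute angles `alpha1 = theta_ankle + phi`,
#' `alpha2 = alpha1 + theta_hip`; the tilt axis passes through the ankle so
#' there is no base translation.
#'
#' @param state a [plant_state()].
#' @param tau applied joint torques `c(ankle, hip)` (N m).
#' @param model a [model_pack()] list (supplies body and floor parameters).
#' @return numeric `c(alpha_ankle, alpha_hip)` (rad/s^2) of the relative
#'   coordinates.
#' @export
plant_dynamics <- function(state, tau, model = model_pack()) {
  acc <- cpp_accel(c(state$theta_ankle, state$theta_hip),
                   c(state$omega_ankle, state$omega_hip),
                   tau, state$t, model)
  if (any(!is.finite(acc))) stop("internal error: singular mass matrix")
  c(alpha_ankle = acc[1], alpha_hip = acc[2])
}

#' Horizontal centre-of-mass position
#'
#' Mass-weighted horizontal position of the two segment COMs using absolute
#' angles, reported in mm anterior of the ankle (forward positive).
#'
#' @param state a [plant_state()] (or numeric `c(theta_ankle, theta_hip)`).
#' @param traj a [floor_trajectory()] used to evaluate the floor angle at
#'   `state$t`; pass `NULL` for a flat floor.
#' @param body a [body_params()].
#' @return COM position (mm).
#' @export
com_position <- function(state, traj = NULL, body = body_params()) {
  if (is.numeric(state)) state <- plant_state(state[1], state[2])
  phi <- if (is.null(traj)) 0 else floor_angle(state$t, traj)$phi
  model <- model_pack(body = body)
  1000 * cpp_com(c(state$theta_ankle, state$theta_hip), phi, model)
}

#' One Euler-Maruyama step of the stochastic plant
#'
#' Deterministic drift advanced by explicit Euler; the supplied noise torque
#' is added to each joint for the step. With `activation_tau = 0` (default)
#' the commanded activations are applied directly, otherwise the internal
#' activation states follow first-order dynamics.
#'
#' @param state a [plant_state()].
#' @param command 4-vector of commanded activations (TA, GC, IL, GM).
#' @param dt step size (s), positive.
#' @param noise per-joint torque perturbation for this step `c(ankle, hip)`
#'   (N m), already scaled by the chosen noise convention.
#' @param model a [model_pack()] list.
#' @return the advanced [plant_state()].
#' @export
plant_step <- function(state, command, dt, noise = c(0, 0),
                       model = model_pack()) {
  stopifnot(dt > 0, length(command) == 4)
  out <- cpp_plant_advance(as_state_vec(state), state$activations,
                           pmin(pmax(command, c(0, 0, 0, 0)), 1),
                           state$t, dt, 1L, matrix(noise, 1, 2), model)
  if (any(!is.finite(out[1, 1:5])))
    stop(sprintf("plant diverged at t = %.3f s", state$t))
  plant_state(out[1, 2], out[1, 3], out[1, 4], out[1, 5], t = out[1, 1],
              activations = pmin(pmax(out[1, 6:9], 0), 1))
}
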