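#' Body segment parameters for the two-link standing model
#'
#' The body is a sagittal-plane double inverted pendulum: link 1 spans
#' ankle to hip (both legs lumped), link 2 is the head-arms-trunk (HAT)
#' segment. Defaults describe a 60-kg, 1.65-m adult from standard
#' anthropometry, calibrated so that the reference standing posture
#' (ankle -0.11 rad, hip 0.18 rad) places the horizontal centre of mass
#' 61 mm anterior of the ankle.
#'
#' @param link1_mass,link2_mass segment masses (kg); must sum to `total_mass`.
#' @param link1_length ankle-to-hip distance (m).
#' @param link1_com,link2_com distance of the segment COM from the proximal
#'   joint (m).
#' @param link1_inertia,link2_inertia moment of inertia about the segment
#'   COM (kg m^2).
#' @param total_mass whole-body mass (kg).
#' @param gravity gravitational acceleration (m/s^2).
#' @return an object of class `body_params`.
#' @export
body_params <- function(total_mass = 60,
                        link1_mass = 19.3, link2_mass = 40.7,
                        link1_length = 0.875,
                        link1_com = 0.39, link2_com = 0.375,
                        link1_inertia = 1.57, link2_inertia = 5.0,
                        gravity = 9.81) {
  stopifnot(link1_mass > 0, link2_mass > 0, link1_length > 0,
            link1_com > 0, link2_com > 0,
            link1_inertia > 0, link2_inertia > 0, gravity > 0,
            link1_com <= link1_length)
  if (abs(link1_mass + link2_mass - total_mass) > 1e-9)
    stop("link1_mass + link2_mass must equal total_mass")
  structure(list(total_mass = total_mass,
                 link1_mass = link1_mass, link2_mass = link2_mass,
                 link1_length = link1_length,
                 link1_com = link1_com, link2_com = link2_com,
                 link1_inertia = link1_inertia, link2_inertia = link2_inertia,
                 gravity = gravity),
            class = "body_params")
}

#' Hill-type muscle parameters
#'
#' Builds the parameter set for one of the four modelled muscles. Torque
#' sign follows the convention that positive joint torque is extensor
#' (pushes the body backward): GC and GM are +1, TA and IL are -1.
#'
#' @param name one of "TA", "GC", "IL", "GM".
#' @param joint "ankle" or "hip".
#' @param torque_sign +1 (extensor/backward) or -1 (flexor/forward).
#' @param f_max maximal isometric force (N).
#' @param moment_arm constant moment arm (m).
#' @param l_opt optimal contractile-element length (m).
#' @param l_slack_passive length below which the passive element is slack (m).
#' @param k_passive passive force scale (N) of the exponential element.
#' @param passive_shape dimensionless exponent of the passive element.
#' @param v_max maximal shortening velocity (m/s).
#' @param fv_curvature Hill force-velocity curvature (dimensionless).
#' @param fl_width width of the Gaussian force-length curve (fraction of
#'   `l_opt`).
#' @param activation_tau first-order activation time constant (s); 0 means
#'   activations are driven directly by the controller.
#' @return an object of class `muscle_params`.
#' @export
muscle_params <- function(name, joint, torque_sign, f_max, moment_arm,
                          l_opt, l_slack_passive = l_opt,
                          k_passive = 0.01 * f_max, passive_shape = 8,
                          v_max = 10 * l_opt, fv_curvature = 0.25,
                          fl_width = 0.45, activation_tau = 0) {
  stopifnot(name %in% c("TA", "GC", "IL", "GM"),
            joint %in% c("ankle", "hip"),
            torque_sign %in% c(-1, 1),
            f_max > 0, moment_arm > 0, l_opt > 0, v_max > 0,
            fv_curvature > 0, fl_width > 0, activation_tau >= 0)
  if (name %in% c("GC", "GM") && torque_sign != 1)
    stop("GC and GM are extensors (torque_sign +1)")
  if (name %in% c("TA", "IL") && torque_sign != -1)
    stop("TA and IL are flexors (torque_sign -1)")
  structure(list(name = name, joint = joint, torque_sign = torque_sign,
                 f_max = f_max, moment_arm = moment_arm, l_opt = l_opt,
                 l_slack_passive = l_slack_passive, k_passive = k_passive,
                 passive_shape = passive_shape, v_max = v_max,
                 fv_curvature = fv_curvature, fl_width = fl_width,
                 activation_tau = activation_tau),
            class = "muscle_params")
}

#' Default four-muscle set (TA, GC, IL, GM)
#'
#' Maximal forces are group-level values (GC stands for the whole
#' plantarflexor group), sized so that holding the reference posture
#' against gravity needs roughly a quarter of GC capacity.
#'
#' @return named list of four [muscle_params()] objects, in the fixed
#'   internal order TA, GC, IL, GM.
#' @export
default_muscles <- function() {
  list(
    TA = muscle_params("TA", "ankle", -1, f_max = 1200, moment_arm = 0.04,
                       l_opt = 0.07),
    GC = muscle_params("GC", "ankle", +1, f_max = 3000, moment_arm = 0.05,
                       l_opt = 0.05),
    IL = muscle_params("IL", "hip", -1, f_max = 1500, moment_arm = 0.05,
                       l_opt = 0.10),
    GM = muscle_params("GM", "hip", +1, f_max = 2000, moment_arm = 0.06,
                       l_opt = 0.14)
  )
}

#' Passive joint stiffness (PD) parameters
#'
#' Intrinsic ankle stiffness is kept sub-critical (below the gravitational
#' toppling stiffness, about 420 N m/rad for the default body) so that the
#' predictive controller must contribute to stability.
#'
#' @param k_ankle,k_hip proportional gains (N m/rad).
#' @param b_ankle,b_hip derivative gains (N m s/rad).
#' @param eq_ankle,eq_hip equilibrium angles (rad); by default the scenario
#'   sets these to the initial posture.
#' @param enabled logical; turn the stiffness contribution off entirely.
#' @return an object of class `stiffness_params`.
#' @export
stiffness_params <- function(k_ankle = 250, k_hip = 150,
                             b_ankle = 80, b_hip = 40,
                             eq_ankle = -0.11, eq_hip = 0.18,
                             enabled = TRUE) {
  stopifnot(k_ankle >= 0, k_hip >= 0, b_ankle >= 0, b_hip >= 0)
  structure(list(k_ankle = k_ankle, k_hip = k_hip,
                 b_ankle = b_ankle, b_hip = b_hip,
                 eq_ankle = eq_ankle, eq_hip = eq_hip, enabled = enabled),
            class = "stiffness_params")
}

#' Floor tilt trajectory (constant-rate ramp)
#'
#' @param tilt_start,tilt_stop ramp start and end times (s).
#' @param max_angle_deg final tilt angle (degrees, toe-up positive).
#' @return an object of class `floor_trajectory`.
#' @export
floor_trajectory <- function(tilt_start = 15, tilt_stop = 16,
                             max_angle_deg = 4) {
  stopifnot(tilt_stop > tilt_start, max_angle_deg >= 0)
  structure(list(tilt_start = tilt_start, tilt_stop = tilt_stop,
                 max_angle = max_angle_deg * pi / 180,
                 max_angle_deg = max_angle_deg,
                 rate = (max_angle_deg * pi / 180) / (tilt_stop - tilt_start)),
            class = "floor_trajectory")
}

#' Joint-torque noise specification
#'
#' Gaussian white torque noise applied as independent series at the ankle
#' and hip. Under the default `"sqrt_dt"` convention `sigma_torque` is the
#' diffusion magnitude of the Euler-Maruyama scheme (per-step torque
#' `sigma/sqrt(dt)`), which at the default noise level produces
#' quiet-stance sway of the order of a millimetre. The alternative
#' `"per_step"` convention reads `sigma_torque` as the SD of the additive
#' torque at the simulation rate.
#'
#' @param sigma_torque noise magnitude (N m), default 0.33.
#' @param convention "sqrt_dt" (default) or "per_step".
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_torque = 0.33, convention = c("sqrt_dt", "per_step")) {
  stopifnot(sigma_torque >= 0)
  convention <- match.arg(convention)
  structure(list(sigma_torque = sigma_torque, convention = convention),
            class = "noise_spec")
}

#' Pack model components into the flat list consumed by the C++ core
#'
#' @param body [body_params()].
#' @param muscles list of four [muscle_params()] in order TA, GC, IL, GM.
#' @param stiffness [stiffness_params()].
#' @param floor [floor_trajectory()].
#' @param th_ref reference posture (rad) at which every muscle sits at its
#'   optimal length; defaults to the stiffness equilibrium.
#' @return plain list understood by the compiled routines.
#' @keywords internal
#' @export
model_pack <- function(body = body_params(), muscles = default_muscles(),
                       stiffness = stiffness_params(), floor = floor_trajectory(),
                       th_ref = c(stiffness$eq_ankle, stiffness$eq_hip)) {
  stopifnot(length(muscles) == 4,
            identical(vapply(muscles, `[[`, "", "name"),
                      c(TA = "TA", GC = "GC", IL = "IL", GM = "GM")))
  mus <- t(vapply(muscles, function(m)
    c(m$f_max, m$moment_arm, m$l_opt, m$l_slack_passive, m$k_passive,
      m$passive_shape, m$v_max, m$fv_curvature, m$fl_width, m$torque_sign),
    numeric(10)))
  list(
    body = c(body$link1_mass, body$link2_mass, body$link1_com, body$link2_com,
             body$link1_length, body$link1_inertia, body$link2_inertia,
             body$gravity),
    muscles = mus,
    th_ref = as.numeric(th_ref),
    act_tau = muscles[[1]]$activation_tau,
    stiffness = c(stiffness$k_ankle, stiffness$k_hip,
                  stiffness$b_ankle, stiffness$b_hip,
                  stiffness$eq_ankle, stiffness$eq_hip,
                  as.numeric(isTRUE(stiffness$enabled))),
    floor = c(floor$tilt_start, floor$tilt_stop, floor$max_angle)
  )
}
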