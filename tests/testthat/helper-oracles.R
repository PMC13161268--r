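# Independent mechanics oracle: equations of motion derived numerically
# from the Lagrangian (finite-difference Euler-Lagrange on the position
# map), sharing only the marker-level geometry with the implementation.

# segment COM positions as a function of the absolute angles q = (a1, a2)
oracle_pos <- function(q, body) {
  list(p1 = c(-body$link1_com * sin(q[1]), body$link1_com * cos(q[1])),
       p2 = c(-(body$link1_length * sin(q[1]) + body$link2_com * sin(q[2])),
              body$link1_length * cos(q[1]) + body$link2_com * cos(q[2])))
}

# complex-step differentiation: exact to machine precision for the
# analytic (trigonometric) position map
oracle_jac <- function(pfun, q, h = 1e-20) {
  J1 <- matrix(0, 2, 2)
  J2 <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    pp <- pfun(q + 1i * e)
    J1[, j] <- Im(pp$p1) / h
    J2[, j] <- Im(pp$p2) / h
  }
  list(J1 = J1, J2 = J2)
}

oracle_T <- function(q, qd, body) {
  J <- oracle_jac(function(qq) oracle_pos(qq, body), q)
  v1 <- J$J1 %*% qd
  v2 <- J$J2 %*% qd
  0.5 * body$link1_mass * sum(v1^2) + 0.5 * body$link1_inertia * qd[1]^2 +
    0.5 * body$link2_mass * sum(v2^2) + 0.5 * body$link2_inertia * qd[2]^2
}

oracle_V <- function(q, body) {
  p <- oracle_pos(q, body)
  body$gravity * (body$link1_mass * p$p1[2] + body$link2_mass * p$p2[2])
}

oracle_energy <- function(q, qd, body) oracle_T(q, qd, body) + oracle_V(q, body)

# mass matrix by polarization of the (exactly quadratic) kinetic energy:
# M_ij = T(e_i + e_j) - T(e_i) - T(e_j) + T(0), exact up to roundoff
oracle_M <- function(q, body) {
  e <- diag(2)
  Tq <- function(qd) oracle_T(q, qd, body)
  T0 <- Tq(c(0, 0))
  M <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2)
    M[i, j] <- Tq(e[, i] + e[, j]) - Tq(e[, i]) - Tq(e[, j]) + T0
  M
}

# accelerations of the absolute angles from numerical Euler-Lagrange:
# M qdd = Q + dT/dq - (dM/dt) qd - dV/dq, with dT/dq_j = qd' dM_j qd / 2
oracle_accel_abs <- function(q, qd, Q, body, h = 1e-5) {
  M <- oracle_M(q, body)
  dM <- lapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- h
    (oracle_M(q + e, body) - oracle_M(q - e, body)) / (2 * h)
  })
  dT_dq <- sapply(1:2, function(j) 0.5 * drop(qd %*% dM[[j]] %*% qd))
  dM_dt <- dM[[1]] * qd[1] + dM[[2]] * qd[2]
  dV_dq <- sapply(1:2, function(j) {
    e <- c(0, 0); e[j] <- 1e-20
    Im(oracle_V(q + 1i * e, body)) / 1e-20
  })
  solve(M, Q + dT_dq - dM_dt %*% qd - dV_dq)
}

# oracle in the package's relative coordinates under applied joint torques
# (tau_ankle between floor and link 1, tau_hip between the links)
oracle_accel_rel <- function(th, om, tau, phi = 0, phidot = 0,
                             body = body_params()) {
  q <- c(th[1] + phi, th[1] + th[2] + phi)
  qd <- c(om[1] + phidot, om[1] + om[2] + phidot)
  Q <- c(tau[1] - tau[2], tau[2])
  qdd <- oracle_accel_abs(q, qd, Q, body)
  c(qdd[1], qdd[2] - qdd[1])           # phi_ddot = 0 on the ramp plateau
}

# passive-plant drift (no muscles, no stiffness, flat floor) used by the
# energy-conservation and instability checks
passive_model <- function(body = body_params()) {
  mus <- lapply(default_muscles(), function(m) {
    m$k_passive <- 0
    m
  })
  model_pack(body = body, muscles = mus,
             stiffness = stiffness_params(enabled = FALSE),
             floor = floor_trajectory(1e6, 1e6 + 1, 0))
}

passive_accel <- function(th, om, model) {
  posturempc:::cpp_accel(th, om, c(0, 0), 0, model)
}

# classical RK4 reference integrator on the same passive drift
rk4_passive <- function(th, om, dt, n, model) {
  f <- function(s) c(s[3], s[4], passive_accel(s[1:2], s[3:4], model))
  s <- c(th, om)
  for (i in seq_len(n)) {
    k1 <- f(s); k2 <- f(s + dt / 2 * k1); k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# explicit Euler on the passive drift (the plant scheme with sigma = 0)
euler_passive <- function(th, om, dt, n, model) {
  s <- c(th, om)
  for (i in seq_len(n)) {
    a <- passive_accel(s[1:2], s[3:4], model)
    s <- s + dt * c(s[3], s[4], a)
  }
  s
}

# short standing scenario used where a full 20-s protocol is unnecessary
short_scenario <- function(...) {
  scenario(duration = 8, floor = floor_trajectory(5, 6, 4),
           preview_enable_time = 3, cs_time = 3, ...)
}
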