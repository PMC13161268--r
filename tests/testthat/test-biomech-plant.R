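test_that("floor ramp is clamped with constant rate on the ramp", {
  traj <- floor_trajectory(15, 16, 4)
  expect_equal(unlist(floor_angle(10, traj)), c(phi = 0, phi_dot = 0, phi_ddot = 0))
  mid <- floor_angle(15.5, traj)
  expect_equal(mid$phi, 2 * pi / 180, tolerance = 1e-12)
  expect_equal(mid$phi_dot, 4 * pi / 180, tolerance = 1e-12)
  expect_equal(mid$phi_ddot, 0)
  late <- floor_angle(18, traj)
  expect_equal(late$phi, 4 * pi / 180, tolerance = 1e-12)
  expect_equal(late$phi_dot, 0)
})

test_that("muscle force matches the closed-form Hill curves", {
  p <- default_muscles()$GC
  # no activation, optimal length at slack, no velocity
  expect_equal(muscle_force(0, p$l_opt, 0, p), 0)
  # full activation at optimum: fL = fV = 1 by construction
  expect_equal(muscle_force(1, p$l_opt, 0, p), p$f_max, tolerance = 1e-12)
  # independent evaluation of the documented closed forms
  a <- 0.5; l <- 1.05 * p$l_opt; v <- 0.1 * p$v_max
  fl <- exp(-((l - p$l_opt) / (p$fl_width * p$l_opt))^2)
  gam <- 0.8 * p$v_max * p$fv_curvature / (1 + p$fv_curvature)
  fv <- (1.8 * v + gam) / (v + gam)
  fp <- p$k_passive * (exp(p$passive_shape * (l - p$l_slack_passive) / p$l_opt) - 1)
  expect_equal(muscle_force(a, l, v, p), a * p$f_max * fl * fv + fp,
               tolerance = 1e-12)
  # shortening at v_max gives zero active force
  expect_equal(muscle_force(1, p$l_opt, -p$v_max, p),
               muscle_force(0, p$l_opt, 0, p), tolerance = 1e-12)
  expect_error(muscle_force(0.5, -0.01, 0, p), "geometry")
})

test_that("muscle kinematics follow the constant-moment-arm map", {
  p <- default_muscles()$GC
  ref <- c(-0.11, 0.18)
  st <- plant_state(ref[1], ref[2])
  lv <- muscle_kinematics(st, p, th_ref = ref)
  expect_equal(lv$l, p$l_opt)
  expect_equal(lv$v, 0)
  # GC shortens (v < 0) while the ankle rotates backward
  st2 <- plant_state(ref[1], ref[2], omega_ankle = 0.1)
  expect_equal(muscle_kinematics(st2, p, th_ref = ref)$v,
               -p$moment_arm * 0.1)
  # l and v agree with finite differences of l along a trajectory
  th_t <- function(t) -0.11 + 0.05 * sin(3 * t)
  om_t <- function(t) 0.15 * cos(3 * t)
  h <- 1e-6
  for (t in c(0.3, 1.1, 2.0)) {
    lv_t <- muscle_kinematics(plant_state(th_t(t), 0.18, om_t(t)), p,
                              th_ref = ref)
    l_p <- muscle_kinematics(plant_state(th_t(t + h), 0.18), p, th_ref = ref)$l
    l_m <- muscle_kinematics(plant_state(th_t(t - h), 0.18), p, th_ref = ref)$l
    expect_equal(lv_t$v, (l_p - l_m) / (2 * h), tolerance = 1e-4)
  }
})

test_that("joint torques sum per-muscle contributions and keep GC backward", {
  model <- model_pack()
  st <- plant_state(-0.11, 0.18)
  expect_equal(unname(joint_torques(st, c(0, 0, 0, 0), model,
                                    stiffness = FALSE)),
               c(0, 0), tolerance = 1e-12)
  # GC alone produces positive (backward) ankle torque, no hip torque
  gc_only <- joint_torques(st, c(0, 0.5, 0, 0), model, stiffness = FALSE)
  expect_gt(gc_only[["tau_ankle"]], 0)
  expect_equal(gc_only[["tau_hip"]], 0)
  # mixed case equals sign * r * F summed muscle by muscle
  mus <- default_muscles()
  set.seed(4)
  for (rep in 1:5) {
    st_r <- plant_state(runif(1, -0.3, 0.2), runif(1, -0.1, 0.4),
                        runif(1, -1, 1), runif(1, -1, 1))
    a <- runif(4)
    expected <- c(0, 0)
    for (i in seq_along(mus)) {
      p <- mus[[i]]
      lv <- muscle_kinematics(st_r, p, th_ref = c(-0.11, 0.18))
      f <- muscle_force(a[i], lv$l, lv$v, p)
      j <- if (p$joint == "ankle") 1 else 2
      expected[j] <- expected[j] + p$torque_sign * p$moment_arm * f
    }
    got <- joint_torques(st_r, a, model, stiffness = FALSE)
    expect_equal(unname(got), expected, tolerance = 1e-9)
  }
})

test_that("rigid-body dynamics match the numerical Euler-Lagrange oracle", {
  body <- body_params()
  model <- passive_model(body)
  st0 <- plant_state(0, 0)
  expect_equal(unname(plant_dynamics(st0, c(0, 0), model)), c(0, 0),
               tolerance = 1e-12)
  # gravity accelerates an anterior lean further forward
  expect_lt(plant_dynamics(plant_state(-0.05, 0), c(0, 0),
                           model)[["alpha_ankle"]], 0)
  set.seed(11)
  n_bad <- 0
  for (i in 1:400) {
    th <- runif(2, -0.6, 0.6); om <- runif(2, -2, 2); tau <- runif(2, -60, 60)
    got <- posturempc:::cpp_accel(th, om, tau, 0, model)
    want <- oracle_accel_rel(th, om, tau, body = body)
    if (max(abs(got - want)) > 1e-8) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
  # with the floor mid-ramp (phi and phi_dot nonzero)
  model_tilt <- model_pack(body = body,
                           muscles = lapply(default_muscles(), function(m) {
                             m$k_passive <- 0; m
                           }),
                           stiffness = stiffness_params(enabled = FALSE),
                           floor = floor_trajectory(15, 16, 4))
  phi <- 2 * pi / 180; phidot <- 4 * pi / 180
  for (i in 1:100) {
    th <- runif(2, -0.4, 0.4); om <- runif(2, -1, 1); tau <- runif(2, -40, 40)
    got <- posturempc:::cpp_accel(th, om, tau, 15.5, model_tilt)
    want <- oracle_accel_rel(th, om, tau, phi = phi, phidot = phidot,
                             body = body)
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-8)
  }
})

test_that("passive mechanical energy is conserved within integrator bounds", {
  body <- body_params()
  model <- passive_model(body)
  E <- function(th, om)
    oracle_energy(c(th[1], th[1] + th[2]), c(om[1], om[1] + om[2]), body)
  # bounded-motion (hanging) configuration keeps the passive trajectory
  # inside the workspace for the full 5-s window
  th0 <- c(pi - 0.05, 0.03)
  for (om0 in list(c(0, 0), c(1, 0.5))) {
    e0 <- E(th0, om0)
    s_euler <- euler_passive(th0, om0, 1e-4, 50000, model)
    expect_lt(abs(E(s_euler[1:2], s_euler[3:4]) - e0) / abs(e0), 1e-3)
  }
  s_rk4 <- rk4_passive(th0, c(0, 0), 1e-3, 5000, model)
  expect_lt(abs(E(s_rk4[1:2], s_rk4[3:4]) - E(th0, c(0, 0))) /
              abs(E(th0, c(0, 0))), 1e-6)
})

test_that("upright standing is an unstable equilibrium", {
  model <- passive_model()
  f <- function(s) c(s[3], s[4], passive_accel(s[1:2], s[3:4], model))
  h <- 1e-6
  J <- sapply(1:4, function(j) {
    e <- rep(0, 4); e[j] <- h
    (f(e) - f(-e)) / (2 * h)
  })
  expect_gt(max(Re(eigen(J)$values)), 0)
})

test_that("ankle torque is monotone in GC and TA activations", {
  model <- model_pack()
  set.seed(21)
  for (rep in 1:10) {
    st <- plant_state(runif(1, -0.3, 0.1), runif(1, 0, 0.3),
                      runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
    lev <- seq(0, 1, by = 0.2)
    tau_gc <- sapply(lev, function(a)
      joint_torques(st, c(0, a, 0, 0), model)[["tau_ankle"]])
    tau_ta <- sapply(lev, function(a)
      joint_torques(st, c(a, 0, 0, 0), model)[["tau_ankle"]])
    expect_true(all(diff(tau_gc) >= 0))
    expect_true(all(diff(tau_ta) <= 0))
  }
})

test_that("Euler-Maruyama stepping is deterministic and scales noise correctly", {
  model <- model_pack()
  st <- plant_state(-0.11, 0.18)
  # sigma = 0 reduces to the plain explicit Euler step
  s1 <- plant_step(st, c(0, 0.2, 0, 0), 1e-3, noise = c(0, 0), model = model)
  s2 <- plant_step(st, c(0, 0.2, 0, 0), 1e-3, noise = c(0, 0), model = model)
  expect_identical(s1, s2)
  # one-step velocity increment variance matches M^-1 Sigma M^-T dt^2
  dt <- 1e-3
  base <- posturempc:::cpp_plant_advance(c(-0.11, 0.18, 0, 0), rep(0, 4),
                                         rep(0, 4), 0, dt, 1L,
                                         matrix(0, 1, 2), model)
  Minv <- sapply(1:2, function(j) {
    tau <- c(0, 0); tau[j] <- 1
    posturempc:::cpp_accel(c(-0.11, 0.18), c(0, 0), tau, 0, model) -
      posturempc:::cpp_accel(c(-0.11, 0.18), c(0, 0), c(0, 0), 0, model)
  })
  sigma_step <- 0.33 / sqrt(dt)
  set.seed(31)
  n <- 4000
  nz <- matrix(rnorm(2 * n, sd = sigma_step), n, 2)
  dom <- t(sapply(seq_len(n), function(k) {
    out <- posturempc:::cpp_plant_advance(c(-0.11, 0.18, 0, 0), rep(0, 4),
                                          rep(0, 4), 0, dt, 1L,
                                          nz[k, , drop = FALSE], model)
    out[1, 4:5] - base[1, 4:5]
  }))
  pred <- diag(Minv %*% diag(rep(sigma_step^2, 2)) %*% t(Minv)) * dt^2
  for (j in 1:2) {
    se <- pred[j] * sqrt(2 / n)
    expect_lt(abs(var(dom[, j]) - pred[j]), 3 * se)
  }
})

test_that("COM position matches hand-computed trigonometry and calibration", {
  expect_equal(com_position(c(0, 0)), 0, tolerance = 1e-12)
  # two-link toy: unit masses, COMs at midpoints, hip angle zero
  toy <- body_params(total_mass = 2, link1_mass = 1, link2_mass = 1,
                     link1_length = 1, link1_com = 0.5, link2_com = 0.5,
                     link1_inertia = 0.1, link2_inertia = 0.1)
  expect_equal(com_position(c(-0.1, 0), body = toy), 1000 * sin(0.1),
               tolerance = 1e-9)
  # calibrated default body puts the reference posture at ~61 mm
  expect_equal(com_position(c(-0.11, 0.18)), 61, tolerance = 0.05)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(body_params(link1_mass = 20, link2_mass = 20),
               "total_mass")
  expect_error(muscle_params("GC", "ankle", -1, 100, 0.05, 0.05),
               "extensor")
  expect_error(floor_trajectory(16, 15, 4))
  expect_error(plant_state(activations = c(0, 2, 0, 0)))
})
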