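test_that("stiffness torque is PD on relative angles", {
  p <- stiffness_params(k_ankle = 300, k_hip = 100, b_ankle = 30, b_hip = 20,
                        eq_ankle = -0.11, eq_hip = 0.18)
  st <- plant_state(-0.11, 0.18)
  expect_equal(unname(stiffness_torque(st, p)), c(0, 0))
  # pure damping opposes the motion
  st_v <- plant_state(-0.11, 0.18, omega_ankle = 0.5, omega_hip = -0.3)
  tq <- stiffness_torque(st_v, p)
  expect_lt(tq[["tau_ankle"]], 0)
  expect_gt(tq[["tau_hip"]], 0)
  # direct formula evaluation
  p2 <- stiffness_params(k_ankle = 300, b_ankle = 0, b_hip = 0, k_hip = 0,
                         eq_ankle = 0, eq_hip = 0)
  expect_equal(stiffness_torque(plant_state(0.1, 0), p2)[["tau_ankle"]], -30)
})

test_that("signed hip channel resolves to mutually exclusive IL/GM", {
  expect_equal(unname(resolve_hip(0.3)), c(0.3, 0))
  expect_equal(unname(resolve_hip(0)), c(0, 0))
  expect_equal(unname(resolve_hip(-0.7)), c(0, 0.7))
  expect_warning(out <- resolve_hip(1.4), "clipped")
  expect_equal(unname(out), c(1, 0))
  for (u in seq(-1, 1, by = 0.1))
    expect_equal(prod(resolve_hip(u)), 0)
})

test_that("MPC stage cost matches its hand evaluation in metre units", {
  cfg <- mpc_config()
  # on-target COM with zero input costs nothing
  expect_equal(mpc_cost(rep(61, 30), matrix(0, 30, 3), c(0, 0, 0), cfg), 0)
  # single step, 10-mm error, u = (0, 0.5, 0), du = 0
  cfg1 <- mpc_config(Np = 1, Nm = 1)
  expect_equal(mpc_cost(71, matrix(c(0, 0.5, 0), 1, 3), c(0, 0.5, 0), cfg1),
               0.01^2 + (0.01 * 0.5)^2, tolerance = 1e-15)
  expect_error(mpc_cost(c(61, 61), matrix(0, 1, 3), c(0, 0, 0), cfg1),
               "lengths differ")
  # default weights
  expect_equal(cfg$w_u, 0.01)
  expect_equal(cfg$w_du, 1)
})

test_that("internal-model prediction is consistent with the plant", {
  # identical sub-steps reproduce the noise-free plant trajectory exactly
  model <- model_pack()
  est <- c(-0.11, 0.18, 0, 0)
  cfg <- mpc_config(Np = 5, Nm = 1, n_sub = 100)
  moves <- c(0, 0.25, 0.1)
  pred <- mpc_predict(moves, est, 0, cfg, model, preview = TRUE)
  act <- resolve_command(moves)
  plant <- posturempc:::cpp_plant_advance(est, rep(0, 4), act, 0, 1e-3,
                                          500L, matrix(0, 500, 2), model)
  idx <- seq(100, 500, by = 100)
  expect_equal(pred$theta_ankle, plant[idx, 2], tolerance = 1e-12)
  expect_equal(pred$omega_hip, plant[idx, 5], tolerance = 1e-12)
  # coarse sub-stepping stays close to the fine plant on a bounded
  # (hanging) trajectory over 3 s
  body <- body_params()
  model_h <- passive_model(body)
  est_h <- c(pi - 2e-4, 1e-4, 0, 0)
  cfg_c <- mpc_config(Np = 30, Nm = 1, n_sub = 10)
  pred_c <- mpc_predict(c(0, 0, 0), est_h, 0, cfg_c, model_h, preview = TRUE)
  fine <- t(sapply(seq(0.1, 3, by = 0.1) / 1e-3, function(n)
    euler_passive(est_h[1:2], est_h[3:4], 1e-3, n, model_h)))
  expect_lt(max(abs(pred_c$theta_ankle - fine[, 1])), 1e-4)
})

test_that("delay compensation reconstructs the true state of a noise-free plant", {
  model <- model_pack()
  est0 <- c(-0.11, 0.18, 0, 0)
  expect_equal(compensate_delay(est0, NULL, 0, 1, model = model), est0)
  # roll a noise-free plant 150 ms under a logged command schedule
  cmds <- matrix(rep(c(0, 0.25, 0.05, 0), each = 150), 150, 4)
  truth <- posturempc:::cpp_plant_advance(est0, rep(0, 4), cmds[1, ], 0,
                                          1e-3, 150L, matrix(0, 150, 2),
                                          model)[150, 2:5]
  est <- compensate_delay(est0, cmds, 0.15, 0.15, model = model)
  expect_equal(as.numeric(est), as.numeric(truth), tolerance = 1e-12)
  expect_warning(out <- compensate_delay(est0, cmds[1:10, ], 0.15, 0.15,
                                         model = model), "history")
  expect_equal(out, est0)
})

test_that("per-tick solve respects bounds and beats baseline candidates", {
  model <- model_pack()
  cfg <- mpc_config(Np = 10, Nm = 2, n_sub = 5)
  est <- c(-0.13, 0.2, 0.1, -0.05)
  u_prev <- c(0, 0.3, 0)
  cmd <- solve_step(est, u_prev, cfg, model, t0 = 0, preview = FALSE,
                    phi_hold = 0)
  fn <- function(u) posturempc:::cpp_mpc_cost(u, est, u_prev, 0, model,
                                              cfg$Np, cfg$Nm, cfg$dt_pred,
                                              cfg$n_sub, cfg$w_u, cfg$w_du,
                                              cfg$x_ref / 1000, FALSE, 0)
  expect_lte(cmd$cost, fn(rep(0, 6)) + 1e-12)
  expect_lte(cmd$cost, fn(rep(u_prev, 2)) + 1e-12)
  expect_true(all(cmd$moves >= rep(c(0, 0, -1), 2) - 1e-12))
  expect_true(all(cmd$moves <= rep(c(1, 1, 1), 2) + 1e-12))
  expect_equal(prod(cmd$activations[3:4]), 0)
})

test_that("tiny-instance solve matches an exhaustive grid oracle", {
  model <- model_pack()
  cfg <- mpc_config(Np = 2, Nm = 1, n_sub = 5)
  est <- c(-0.11, 0.18, 0, 0)
  u_prev <- c(0, 0.2, 0)
  fn <- function(u) posturempc:::cpp_mpc_cost(u, est, u_prev, 0, model,
                                              cfg$Np, cfg$Nm, cfg$dt_pred,
                                              cfg$n_sub, cfg$w_u, cfg$w_du,
                                              cfg$x_ref / 1000, FALSE, 0)
  grid1 <- seq(0, 1, length.out = 21)
  grid_hip <- seq(-1, 1, length.out = 21)
  best <- Inf
  for (ta in grid1) for (gc in grid1) for (hp in grid_hip) {
    v <- fn(c(ta, gc, hp))
    if (v < best) best <- v
  }
  cmd <- solve_step(est, u_prev, cfg, model, t0 = 0, preview = FALSE,
                    phi_hold = 0)
  expect_lte(cmd$cost, best + 1e-6)
})

test_that("LLR window modifies only GC and only inside the window", {
  cfg <- llr_config(enabled = TRUE)
  cmd <- list(u = c(0, 0.2, 0.1), activations = c(0, 0.2, 0.1, 0))
  inside <- apply_llr(cmd, 15.15, 15, cfg)
  expect_equal(inside$activations[2], 0.7)
  expect_equal(inside$activations[c(1, 3, 4)], cmd$activations[c(1, 3, 4)])
  before <- apply_llr(cmd, 15.05, 15, cfg)
  expect_identical(before, cmd)
  after <- apply_llr(cmd, 15.25, 15, cfg)
  expect_identical(after, cmd)
  clip <- apply_llr(list(u = c(0, 0.8, 0), activations = c(0, 0.8, 0, 0)),
                    15.15, 15, cfg)
  expect_equal(clip$activations[2], 1)
  override <- apply_llr(cmd, 15.15, 15,
                        llr_config(TRUE, combine = "override"))
  expect_equal(override$activations[2], 0.5)
})

test_that("warm-started receding-horizon cost does not jump in a static world", {
  model <- model_pack()
  cfg <- mpc_config(Np = 10, Nm = 2, n_sub = 5)
  est <- c(-0.11, 0.18, 0, 0)
  cmd1 <- solve_step(est, c(0, 0.25, 0), cfg, model, t0 = 0,
                     preview = FALSE, phi_hold = 0)
  warm <- c(cmd1$moves[4:6], cmd1$moves[4:6])
  cmd2 <- solve_step(est, cmd1$u, cfg, model, t0 = 0.1, preview = FALSE,
                     phi_hold = 0, warm_start = warm)
  expect_lte(cmd2$cost, cmd1$cost * 1.05 + 1e-8)
})
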