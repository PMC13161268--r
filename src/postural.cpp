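// Core numerics for the two-link standing model:
//  - sagittal-plane double inverted pendulum on a prescribed tilting floor
//  - four Hill-type muscles (TA, GC at the ankle; IL, GM at the hip)
//  - passive joint stiffness (PD on relative angles)
//  - Euler-Maruyama plant stepping with additive joint-torque noise
//  - noise-free internal-model rollouts and the MPC stage cost
//
// Conventions (shared with the R layer):
//   th[0] = ankle angle, shank relative to the floor normal (negative = anterior lean)
//   th[1] = hip angle, HAT relative to the shank (positive = posterior lean)
//   absolute angles from vertical: a1 = th[0] + phi, a2 = a1 + th[1]
//   COM x is anterior-positive; x = -sum(m r sin(alpha)) / M  (metres here)
//   positive joint torque = extensor/backward (increases the joint angle)
//   muscle order: 0 TA (-1, ankle), 1 GC (+1, ankle), 2 IL (-1, hip), 3 GM (+1, hip)

#include <Rcpp.h>
using namespace Rcpp;

struct Model {
  // body
  double m1, m2, c1, c2, l1, I1, I2, g;
  // muscles (4)
  double fmax[4], r[4], lopt[4], lslack[4], kpass[4], pshape[4],
         vmax[4], fvk[4], flw[4], sgn[4];
  int joint[4];
  double thref[2];       // posture at which every muscle sits at optimal length
  double act_tau;        // first-order activation time constant, 0 = direct drive
  // passive stiffness (PD on relative angles)
  double ks[2], bs[2], theq[2];
  int stiffness_on;
  // floor ramp
  double tilt_start, tilt_stop, tilt_max;
};

static Model parse_model(const List& m) {
  Model M;
  NumericVector body = m["body"];          // m1 m2 c1 c2 l1 I1 I2 g
  M.m1 = body[0]; M.m2 = body[1]; M.c1 = body[2]; M.c2 = body[3];
  M.l1 = body[4]; M.I1 = body[5]; M.I2 = body[6]; M.g = body[7];
  NumericMatrix mus = m["muscles"];        // 4 rows x 10 cols
  for (int i = 0; i < 4; ++i) {
    M.fmax[i]  = mus(i, 0); M.r[i]      = mus(i, 1); M.lopt[i] = mus(i, 2);
    M.lslack[i]= mus(i, 3); M.kpass[i]  = mus(i, 4); M.pshape[i] = mus(i, 5);
    M.vmax[i]  = mus(i, 6); M.fvk[i]    = mus(i, 7); M.flw[i]  = mus(i, 8);
    M.sgn[i]   = mus(i, 9);
    M.joint[i] = (i < 2) ? 0 : 1;
  }
  NumericVector thref = m["th_ref"];
  M.thref[0] = thref[0]; M.thref[1] = thref[1];
  M.act_tau = as<double>(m["act_tau"]);
  NumericVector st = m["stiffness"];       // k_a k_h b_a b_h eq_a eq_h on
  M.ks[0] = st[0]; M.ks[1] = st[1]; M.bs[0] = st[2]; M.bs[1] = st[3];
  M.theq[0] = st[4]; M.theq[1] = st[5]; M.stiffness_on = (int) st[6];
  NumericVector fl = m["floor"];           // tilt_start tilt_stop tilt_max(rad)
  M.tilt_start = fl[0]; M.tilt_stop = fl[1]; M.tilt_max = fl[2];
  return M;
}

// piecewise-linear floor ramp, clamped; phi_ddot reported as 0
static inline void floor_angle(double t, const Model& M,
                               double& phi, double& phidot) {
  if (M.tilt_max <= 0.0 || t <= M.tilt_start) { phi = 0.0; phidot = 0.0; return; }
  double rate = M.tilt_max / (M.tilt_stop - M.tilt_start);
  if (t >= M.tilt_stop) { phi = M.tilt_max; phidot = 0.0; return; }
  phi = rate * (t - M.tilt_start);
  phidot = rate;
}

// Hill force-length (Gaussian), force-velocity (hyperbolic, eccentric
// plateau with slope-matched transition), exponential passive element
static inline double muscle_force(double a, double l, double v,
                                  int i, const Model& M) {
  double fl = std::exp(-std::pow((l - M.lopt[i]) / (M.flw[i] * M.lopt[i]), 2.0));
  double fv;
  double vmax = M.vmax[i], k = M.fvk[i];
  if (v <= 0.0) {                       // shortening
    double vv = std::max(v, -vmax);
    fv = (vmax + vv) / (vmax - vv / k);
  } else {                              // lengthening, plateau at 1.8
    double gam = 0.8 * vmax * k / (1.0 + k);   // slope continuity at v = 0
    fv = (1.8 * v + gam) / (v + gam);
  }
  double fp = 0.0;
  if (l > M.lslack[i])
    fp = M.kpass[i] * (std::exp(M.pshape[i] * (l - M.lslack[i]) / M.lopt[i]) - 1.0);
  double f = a * M.fmax[i] * fl * fv + fp;
  return (f > 0.0) ? f : 0.0;
}

static inline void muscle_geom(const double th[2], const double om[2],
                               int i, const Model& M, double& l, double& v) {
  int j = M.joint[i];
  l = M.lopt[i] - M.sgn[i] * M.r[i] * (th[j] - M.thref[j]);
  v = -M.sgn[i] * M.r[i] * om[j];
}

// total joint torques: muscles (+ optional PD stiffness) + additive noise
static inline void joint_torques(const double th[2], const double om[2],
                                 const double act[4], const Model& M,
                                 const double noise[2], double tau[2]) {
  tau[0] = noise[0]; tau[1] = noise[1];
  for (int i = 0; i < 4; ++i) {
    double l, v;
    muscle_geom(th, om, i, M, l, v);
    double f = muscle_force(act[i], l, v, i, M);
    tau[M.joint[i]] += M.sgn[i] * M.r[i] * f;
  }
  if (M.stiffness_on) {
    for (int j = 0; j < 2; ++j)
      tau[j] += -M.ks[j] * (th[j] - M.theq[j]) - M.bs[j] * om[j];
  }
}

// accelerations of the relative coordinates; base rotation phi is prescribed
// (tilt axis through the ankle, phi_ddot treated as 0)
static inline void accel(const double th[2], const double om[2],
                         const double tau[2], double phi, double phidot,
                         const Model& M, double thdd[2]) {
  double a1 = th[0] + phi, a2 = a1 + th[1];
  double ad1 = om[0] + phidot, ad2 = ad1 + om[1];
  double D = a1 - a2;                    // = -th[1]
  double M11 = M.I1 + M.m1 * M.c1 * M.c1 + M.m2 * M.l1 * M.l1;
  double M12 = M.m2 * M.l1 * M.c2 * std::cos(D);
  double M22 = M.I2 + M.m2 * M.c2 * M.c2;
  // generalized forces on absolute angles: Q1 = tau_a - tau_h, Q2 = tau_h
  double h = M.m2 * M.l1 * M.c2 * std::sin(D);
  double rhs1 = (tau[0] - tau[1]) - h * ad2 * ad2
              + M.g * (M.m1 * M.c1 + M.m2 * M.l1) * std::sin(a1);
  double rhs2 = tau[1] + h * ad1 * ad1 + M.g * M.m2 * M.c2 * std::sin(a2);
  double det = M11 * M22 - M12 * M12;
  double aa1 = ( M22 * rhs1 - M12 * rhs2) / det;
  double aa2 = (-M12 * rhs1 + M11 * rhs2) / det;
  thdd[0] = aa1;            // phi_ddot = 0
  thdd[1] = aa2 - aa1;
}

static inline double com_x(const double th[2], double phi, const Model& M) {
  double a1 = th[0] + phi, a2 = a1 + th[1];
  return -(M.m1 * M.c1 * std::sin(a1)
           + M.m2 * (M.l1 * std::sin(a1) + M.c2 * std::sin(a2)))
         / (M.m1 + M.m2);
}

// one Euler(-Maruyama) step in place; returns false on non-finite state
static inline bool euler_step(double th[2], double om[2], double act[4],
                              const double cmd[4], double t, double dt,
                              const double noise[2], const Model& M) {
  if (M.act_tau > 0.0) {
    for (int i = 0; i < 4; ++i) act[i] += dt * (cmd[i] - act[i]) / M.act_tau;
  } else {
    for (int i = 0; i < 4; ++i) act[i] = cmd[i];
  }
  double phi, phidot;
  floor_angle(t, M, phi, phidot);
  double tau[2], thdd[2];
  joint_torques(th, om, act, M, noise, tau);
  accel(th, om, tau, phi, phidot, M, thdd);
  th[0] += dt * om[0]; th[1] += dt * om[1];
  om[0] += dt * thdd[0]; om[1] += dt * thdd[1];
  return R_finite(th[0]) && R_finite(th[1]) && R_finite(om[0]) && R_finite(om[1]);
}

// ---------------------------------------------------------------- exports --

// [[Rcpp::export]]
NumericVector cpp_floor_angle(double t, double tilt_start, double tilt_stop,
                              double tilt_max) {
  Model M; M.tilt_start = tilt_start; M.tilt_stop = tilt_stop; M.tilt_max = tilt_max;
  double phi, phidot;
  floor_angle(t, M, phi, phidot);
  return NumericVector::create(phi, phidot, 0.0);
}

// [[Rcpp::export]]
double cpp_muscle_force(double a, double l, double v, int idx, List model) {
  Model M = parse_model(model);
  return muscle_force(a, l, v, idx, M);
}

// [[Rcpp::export]]
NumericVector cpp_muscle_geom(NumericVector th, NumericVector om, int idx,
                              List model) {
  Model M = parse_model(model);
  double thv[2] = {th[0], th[1]}, omv[2] = {om[0], om[1]};
  double l, v;
  muscle_geom(thv, omv, idx, M, l, v);
  return NumericVector::create(l, v);
}

// [[Rcpp::export]]
NumericVector cpp_joint_torques(NumericVector th, NumericVector om,
                                NumericVector act, List model,
                                NumericVector noise, bool stiffness) {
  Model M = parse_model(model);
  if (!stiffness) M.stiffness_on = 0;
  double thv[2] = {th[0], th[1]}, omv[2] = {om[0], om[1]};
  double a[4] = {act[0], act[1], act[2], act[3]};
  double nz[2] = {noise[0], noise[1]}, tau[2];
  joint_torques(thv, omv, a, M, nz, tau);
  return NumericVector::create(tau[0], tau[1]);
}

// [[Rcpp::export]]
NumericVector cpp_accel(NumericVector th, NumericVector om, NumericVector tau,
                        double t, List model) {
  Model M = parse_model(model);
  double phi, phidot;
  floor_angle(t, M, phi, phidot);
  double thv[2] = {th[0], th[1]}, omv[2] = {om[0], om[1]};
  double tv[2] = {tau[0], tau[1]}, thdd[2];
  accel(thv, omv, tv, phi, phidot, M, thdd);
  return NumericVector::create(thdd[0], thdd[1]);
}

// [[Rcpp::export]]
double cpp_com(NumericVector th, double phi, List model) {
  Model M = parse_model(model);
  double thv[2] = {th[0], th[1]};
  return com_x(thv, phi, M);
}

// Advance the stochastic plant n steps under a constant command.
// noise: n x 2 matrix of torque perturbations (N*m, already scaled).
// Returns an n x 9 matrix (t, th_a, th_h, om_a, om_h, a_TA, a_GC, a_IL, a_GM);
// stops early (rows filled with NA) if the state diverges.
// [[Rcpp::export]]
NumericMatrix cpp_plant_advance(NumericVector state, NumericVector act0,
                                NumericVector cmd, double t0, double dt,
                                int n, NumericMatrix noise, List model) {
  Model M = parse_model(model);
  double th[2] = {state[0], state[1]}, om[2] = {state[2], state[3]};
  double act[4] = {act0[0], act0[1], act0[2], act0[3]};
  double cd[4] = {cmd[0], cmd[1], cmd[2], cmd[3]};
  NumericMatrix out(n, 9);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int s = 0; s < n; ++s) {
    double nz[2] = {noise(s, 0), noise(s, 1)};
    bool ok = euler_step(th, om, act, cd, t0 + s * dt, dt, nz, M);
    out(s, 0) = t0 + (s + 1) * dt;
    out(s, 1) = th[0]; out(s, 2) = th[1]; out(s, 3) = om[0]; out(s, 4) = om[1];
    out(s, 5) = act[0]; out(s, 6) = act[1]; out(s, 7) = act[2]; out(s, 8) = act[3];
    if (!ok || std::fabs(th[0]) > 1.5 || std::fabs(th[1]) > 1.5) break;
  }
  return out;
}

// Noise-free rollout of the internal model under a logged per-step command
// schedule (n x 4), using the actual floor trajectory. Used to roll a delayed
// measurement forward to the present. Returns the final (th, om) state.
// [[Rcpp::export]]
NumericVector cpp_rollout_logged(NumericVector state, NumericMatrix cmds,
                                 double t0, double dt, List model) {
  Model M = parse_model(model);
  double th[2] = {state[0], state[1]}, om[2] = {state[2], state[3]};
  double act[4] = {0, 0, 0, 0};
  double nz[2] = {0.0, 0.0};
  int n = cmds.nrow();
  for (int s = 0; s < n; ++s) {
    double cd[4] = {cmds(s, 0), cmds(s, 1), cmds(s, 2), cmds(s, 3)};
    if (M.act_tau <= 0.0) { act[0]=cd[0]; act[1]=cd[1]; act[2]=cd[2]; act[3]=cd[3]; }
    if (!euler_step(th, om, act, cd, t0 + s * dt, dt, nz, M)) break;
  }
  return NumericVector::create(th[0], th[1], om[0], om[1]);
}

// map the three MPC channels to four activations (IL/GM mutually exclusive)
static inline void resolve3(const double u[3], double act[4]) {
  act[0] = u[0]; act[1] = u[1];
  act[2] = (u[2] > 0.0) ?  u[2] : 0.0;
  act[3] = (u[2] < 0.0) ? -u[2] : 0.0;
}

// Internal-model rollout over the prediction horizon.
// u: 3*Nm decision vector (moves; last move held to the horizon end).
// If preview is false the floor is frozen at phi_hold for the whole horizon.
// Writes Np COM values (m) and returns false on divergence.
static bool predict_com(const double* u, const double est[4], double t0,
                        const Model& M, int Np, int Nm, double dtp, int nsub,
                        bool preview, double phi_hold, double* com_out,
                        double* traj_out /* may be null; Np x 4 row-major */) {
  Model Mi = M;
  if (!preview) {                         // freeze the floor at its current angle
    Mi.tilt_max = phi_hold; Mi.tilt_start = -2.0; Mi.tilt_stop = -1.0;
  }
  double th[2] = {est[0], est[1]}, om[2] = {est[2], est[3]};
  double act[4], dts = dtp / nsub;
  resolve3(u, act);                       // initial activation state if lag is on
  for (int k = 0; k < Np; ++k) {
    int mk = (k < Nm) ? k : (Nm - 1);
    double cd[4];
    resolve3(u + 3 * mk, cd);
    double nz[2] = {0.0, 0.0};
    // large angles are allowed here: a falling rollout keeps a finite,
    // smoothly growing COM error so the solver retains gradient information
    for (int s = 0; s < nsub; ++s) {
      double t = t0 + k * dtp + s * dts;
      if (!euler_step(th, om, act, cd, t, dts, nz, Mi)) return false;
    }
    double phi, phidot;
    floor_angle(t0 + (k + 1) * dtp, Mi, phi, phidot);
    com_out[k] = com_x(th, phi, Mi);
    if (traj_out) {
      traj_out[4 * k] = th[0]; traj_out[4 * k + 1] = th[1];
      traj_out[4 * k + 2] = om[0]; traj_out[4 * k + 3] = om[1];
    }
  }
  return true;
}

// stage cost: squared COM error (m) + (wu*u)^2 + (wdu*du)^2 over the horizon
static double horizon_cost(const double* u, const double* com, int Np, int Nm,
                           const double uprev[3], double wu, double wdu,
                           double xref_m) {
  double J = 0.0;
  double last[3] = {uprev[0], uprev[1], uprev[2]};
  for (int k = 0; k < Np; ++k) {
    int mk = (k < Nm) ? k : (Nm - 1);
    const double* uk = u + 3 * mk;
    double e = com[k] - xref_m;
    J += e * e;
    for (int c = 0; c < 3; ++c) {
      double du = uk[c] - last[c];
      J += wu * uk[c] * wu * uk[c] + wdu * du * wdu * du;
      last[c] = uk[c];
    }
  }
  return J;
}

// [[Rcpp::export]]
double cpp_mpc_cost(NumericVector u, NumericVector est, NumericVector uprev,
                    double t0, List model, int Np, int Nm, double dtp,
                    int nsub, double wu, double wdu, double xref_m,
                    bool preview, double phi_hold) {
  Model M = parse_model(model);
  std::vector<double> com(Np);
  double es[4] = {est[0], est[1], est[2], est[3]};
  double up[3] = {uprev[0], uprev[1], uprev[2]};
  if (!predict_com(u.begin(), es, t0, M, Np, Nm, dtp, nsub, preview, phi_hold,
                   com.data(), nullptr))
    return 1e12;                         // divergence within the horizon
  return horizon_cost(u.begin(), com.data(), Np, Nm, up, wu, wdu, xref_m);
}

// central-difference gradient of cpp_mpc_cost in the decision vector
// [[Rcpp::export]]
NumericVector cpp_mpc_grad(NumericVector u, NumericVector est,
                           NumericVector uprev, double t0, List model,
                           int Np, int Nm, double dtp, int nsub, double wu,
                           double wdu, double xref_m, bool preview,
                           double phi_hold, double h) {
  Model M = parse_model(model);
  int nu = u.size();
  std::vector<double> com(Np), uu(u.begin(), u.end());
  double es[4] = {est[0], est[1], est[2], est[3]};
  double up[3] = {uprev[0], uprev[1], uprev[2]};
  NumericVector g(nu);
  for (int i = 0; i < nu; ++i) {
    double u0 = uu[i];
    uu[i] = u0 + h;
    double fp = predict_com(uu.data(), es, t0, M, Np, Nm, dtp, nsub, preview,
                            phi_hold, com.data(), nullptr)
                ? horizon_cost(uu.data(), com.data(), Np, Nm, up, wu, wdu, xref_m)
                : 1e12;
    uu[i] = u0 - h;
    double fm = predict_com(uu.data(), es, t0, M, Np, Nm, dtp, nsub, preview,
                            phi_hold, com.data(), nullptr)
                ? horizon_cost(uu.data(), com.data(), Np, Nm, up, wu, wdu, xref_m)
                : 1e12;
    uu[i] = u0;
    g[i] = (fp - fm) / (2.0 * h);
  }
  return g;
}

// full predicted trajectory for the predict() API and tests:
// Np x 6 matrix (t, th_a, th_h, om_a, om_h, com_m)
// [[Rcpp::export]]
NumericMatrix cpp_predict_traj(NumericVector u, NumericVector est, double t0,
                               List model, int Np, int Nm, double dtp,
                               int nsub, bool preview, double phi_hold) {
  Model M = parse_model(model);
  std::vector<double> com(Np), traj(4 * Np);
  double es[4] = {est[0], est[1], est[2], est[3]};
  bool ok = predict_com(u.begin(), es, t0, M, Np, Nm, dtp, nsub, preview,
                        phi_hold, com.data(), traj.data());
  NumericMatrix out(Np, 6);
  std::fill(out.begin(), out.end(), NA_REAL);
  int n = ok ? Np : 0;
  for (int k = 0; k < n; ++k) {
    out(k, 0) = t0 + (k + 1) * dtp;
    out(k, 1) = traj[4 * k]; out(k, 2) = traj[4 * k + 1];
    out(k, 3) = traj[4 * k + 2]; out(k, 4) = traj[4 * k + 3];
    out(k, 5) = com[k];
  }
  return out;
}
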