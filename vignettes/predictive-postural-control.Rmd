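---
title: "Predictive postural control: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive postural control: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The phenomenon and the model

Humans who know a backward floor tilt is coming shift their centre of
mass (COM) forward during the warning period, and they do so while
*increasing* gastrocnemius (GC) activity — a muscle whose ankle torque
points backward, against the direction of travel. `posturempc` asks
whether this seemingly paradoxical coordination falls out of predictive
optimal control, by closing the loop between a stochastic musculoskeletal
standing model and a model predictive controller (MPC) that previews the
scheduled disturbance.

## Plant

The body is a sagittal-plane double inverted pendulum: link 1 is both
legs (ankle to hip), link 2 the head–arms–trunk (HAT) segment. The floor
tilts about an axis through the ankle, so the floor angle $\varphi(t)$
enters the rigid-body dynamics only through the absolute segment angles
$\alpha_1 = \theta_{ankle} + \varphi$, $\alpha_2 = \alpha_1 +
\theta_{hip}$; there is no base translation, and the ramp's angular
acceleration is treated as zero (the ramp is slow, 4°/s). Angle
conventions: negative ankle angle = anterior lean, positive hip angle =
posterior lean of the HAT, COM measured in mm anterior of the ankle.

Four Hill-type muscles act through constant moment arms: TA and GC at
the ankle, IL and GM at the hip. Active force is
$a\,F_{max}\,f_L(\ell)\,f_V(v)$ with a Gaussian force–length curve
(width 0.45 $\ell_{opt}$), a hyperbolic force–velocity curve with an
eccentric plateau at 1.8 $F_{max}$ (slope-matched at $v=0$), and an
exponential passive element that engages beyond the slack length.
Muscle length is linear in the joint angle
($\ell = \ell_{opt} - s\,r\,(\theta - \theta_{ref})$, $s$ the torque
sign), with the reference posture set to the trial's initial posture.
Activation is the control input directly (`activation_tau = 0` by
default); a first-order activation lag is available as an option.

A passive proportional–derivative "intrinsic stiffness" acts on the
relative joint angles, with the equilibrium at the initial posture.
Biological noise is additive Gaussian white torque, generated as
independent series at the ankle and the hip, and the plant is advanced
by the Euler–Maruyama scheme at 1000 Hz.

## Controller

Every `control_period` (0.1 s) the controller:

1. receives the plant state with a 150-ms sensory delay and rolls it
   forward through the noise-free internal model under the logged
   applied commands (`compensate_delay()`);
2. minimises over $N_m = 2$ moves (three channels each: TA, GC, and a
   signed hip channel resolved to IL *or* GM, never both) the horizon
   cost
   $$J = \sum_{k=1}^{N_p} (x_{COM,k} - x_{ref})^2 + (w_u u_k)^2 +
   (w_{\delta u}\,\delta u_k)^2,$$
   with $N_p = 30$ prediction steps of 0.1 s (a 3-s horizon spanning cue
   to tilt end), the last move held constant after the second step
   (move blocking), and the scheduled floor trajectory supplied to the
   internal model from the preview-enable time (13 s, the simulation's
   cue) onward — before that, the floor is assumed frozen at its current
   angle;
3. applies the first move, held for one control period (zero-order
   hold at the 1000-Hz plant).

COM error in the cost is expressed in metres. This is the only unit
pairing under which the printed weights ($w_u = 0.01$,
$w_{\delta u} = 1$, inputs on $[0,1]$) leave all three terms
commensurate: with millimetres the input terms would be numerically
irrelevant across the entire input-weight sweep, contradicting the
strong behavioural effect of that sweep.

The per-tick problem is solved with projected quasi-Newton iterations
(L-BFGS-B over the 6-vector with box bounds, central-difference
gradients computed in compiled code), warm-started from the shifted
previous solution. The all-zeros sequence and the repeated previous
command are always evaluated as explicit candidates, so the returned
cost never exceeds either. When an internal-model rollout topples, the
rollout is *not* truncated: the falling trajectory keeps a finite,
smoothly growing COM error. This matters — truncating with a constant
penalty makes the cost flat precisely in the regimes (backward-leaning
targets) where every naive plan falls within the horizon, and a
flat-cost solver never finds the stabilising inputs. Only non-finite
states return the guard value.

An optional long-latency-reflex (LLR) term adds a constant 50% GC
activation during a 100-ms window starting 100 ms after tilt onset
(add-then-clip by default; an override mode exists).

# Calibration

The reference publication takes its body, muscle and stiffness values
from supplementary tables that are not part of the text this package was
built from, so the defaults here are the package's own calibration, done
once and then frozen:

* **Body** (60 kg, 1.65 m, standard anthropometry): segment masses
  19.3/40.7 kg, ankle–hip length 0.875 m; the HAT COM offset (0.375 m)
  was adjusted so that the reference standing posture (ankle −0.11 rad,
  hip 0.18 rad) puts the COM 61 mm anterior of the ankle — the one
  printed kinematic constraint available.
* **Stiffness**: ankle 250, hip 150 N·m/rad; damping 80, 40 N·m·s/rad.
  The ankle gain is deliberately sub-critical (gravitational toppling
  stiffness ≈ 420 N·m/rad for this body), so the controller must act;
  within that regime the gains were chosen so that (a) the closed loop
  stands for 20 s across the full COM-target sweep (−50 to +100 mm),
  (b) the gravity-load changes during the cue period flow through GC
  rather than being absorbed passively — which is what produces the
  strong trial-level coupling between COM shift and GC slope
  ($R^2 \approx 0.5$–$0.7$ depending on the cohort) — and (c) the mean cue-period GC slope is
  positive with TA an order of magnitude smaller.
* **Muscles**: group-level maximal forces (GC stands for the whole
  plantarflexor group, 3000 N at a 5-cm moment arm), sized so holding
  the reference posture needs ≈ 24% GC activation.
* **Noise**: the stated 0.33 N·m white-noise magnitude is read as the
  diffusion coefficient of the Euler–Maruyama scheme (per-step torque
  SD $0.33/\sqrt{dt}$). The alternative reading — 0.33 N·m per step at
  1000 Hz — produces quiet-stance COM sway of ~0.05 mm, visibly
  inconsistent with the cyclic millimetre-scale sway the phase
  portraits show, and it leaves essentially no trial-to-trial
  variability for the COM-shift/GC-slope regression to act on. Both
  conventions are available (`noise_convention`).

All of these are plain function arguments; nothing in the package
depends on the defaults being *the* values.

## What the model reproduces, and one known shortfall

With the frozen defaults the closed loop reproduces, qualitatively and
mostly quantitatively: the forward COM shift beginning at the cue with
GC (not TA) carrying it; the trial-level regression of GC slope on COM
shift with $R^2 \approx 0.5$–$0.7$; the near-constancy of the shift across
initial/target postures, with TA taking over at backward-leaning
targets; the monotone growth of the shift with the previewed tilt
magnitude; the monotone drop of integrated squared activation as the
input weight grows; no shift at all without preview; and the
impulse-like GC burst when the LLR term is enabled.

The one quantitative shortfall is the *magnitude* of the anticipatory
shift: ~9–15 mm at a 4° tilt against a reported 20–30 mm (the model
reaches ~28 mm at 8°). We explored stiffness 100–380 N·m/rad, both
equilibrium conventions, damping 20–120, GC strength 1500–3000 N,
activation lags up to 0.1 s, control ticks from 10 to 100 Hz,
internal-model resolutions of 1–10 sub-steps per prediction step, both
noise conventions, and verified by multi-start that the per-tick solver
reaches the global optimum. The shift stays in that band because, for
this plant, the optimiser can plan constant-input trajectories that ride
the gravitational saddle through the tilt at small predicted cost, so
larger pre-positioning is simply not optimal. Reproducing the larger
value presumably requires the unpublished parameter tables. We report
the honest number rather than inflating it.

# The synthetic marker/EMG generator

`synth_trial()`/`synth_cohort()` emulate the *recordings* the analysis
pipeline consumes, with known ground truth: 30-s trials at 300 Hz, a 4°
tilt over 0.81 s at 20 s, a cue 2–3 s before the tilt (cue condition),
quiet sway as a band-limited oscillation (period 3–5 s, amplitude 3–5 mm
plus slow filtered noise), a cue-conditioned smooth forward COM ramp,
a carried-backward-then-recover tilt response, marker noise, and GC/TA
envelopes with a cue-period ramp and a post-tilt burst at a configurable
latency (85 ms by default). EMG is stored both as a %MVC envelope and as
an envelope-modulated white-noise carrier scaled so that the analysis
chain (1-Hz high-pass, rectification, 10-Hz low-pass, %MVC) recovers the
envelope.

What the generator does *not* emulate: realistic raw interference EMG at
the native 2000-Hz rate, marker occlusions or labelling errors, 3-D
kinematics, foot–ground mechanics, and any within-session adaptation.
Tests passing on synthetic cohorts therefore validate the *pipeline
arithmetic* (filters, differentiation, COM reconstruction, test
statistics, error rates), not the physiological realism of real
recordings.

Two statistical properties are checked explicitly on the generator: the
per-subject cue test keeps its nominal type-I error on null cohorts
(5% ± 3% over 200 cohorts), and a paper-scale injected effect (25 mm at
20 trials/condition) is detected in ≥ 95% of cohorts.

# Numerical choices

* Plant integration: explicit Euler–Maruyama at $dt = 1$ ms. In the
  bounded-motion regime the passive drift conserves energy to
  $<10^{-3}$ relative over 5 s at $dt = 10^{-4}$ s (an RK4 reference
  drifts $<10^{-6}$); the scheme matches the reference model exactly in
  expectation and is what the stochastic formulation calls for.
* Internal-model rollouts: 10 Euler sub-steps per 0.1-s prediction step
  (configurable). One sub-step reproduces a plain discrete-time internal
  model; 10 keeps the rollout within $10^{-4}$ rad of a 1-ms reference
  on bounded trajectories.
* Rigid-body dynamics are verified against an independent numerical
  Euler–Lagrange oracle (mass matrix by polarization of the kinetic
  energy, complex-step position Jacobians) to $10^{-8}$ on 1000 random
  states.
* Delay compensation replays the exactly-known past state through the
  internal model; during the first 150 ms of a trial the initial state
  itself is used (it is known exactly at rest).
* Zero-phase filtering (forward–backward, odd-reflection padding,
  steady-state initial conditions) is the default everywhere so latency
  measures are unbiased; single-pass filtering is a flag. The effective
  order of the zero-phase variant is doubled.
* Five-point differentiation uses the interior central stencil (exact
  through degree 4) and same-order one-sided stencils on the two edge
  samples.
* Tie-breaks: `first_peak_latency()` returns the *first* local maximum
  above baseline + 5 %MVC, not the largest; the IL/GM channel maps
  exactly zero hip command to both muscles off.
* A fall is a reportable outcome: `run_trial()` truncates at the failure
  time and flags `fell`, and sweep summaries carry the flag.

## Problem sizes used by the test suite

The checked-in tests run the full 20-s protocol where the claim needs it
(baseline cohort of 20 trials, preview-off cohort of 20) and reduced
renderings elsewhere: 5 trials per grid point on a 6-point input-weight
grid and a {1, 2, 4, 8}° tilt grid, 3 targets for the target sweep, and
200 + 200 synthetic cohorts for the error-rate checks. An 8-s variant of
the scenario (tilt at 5 s, preview at 3 s) backs the structural tests.
These sizes are the package's rendering of the protocols at desk scale;
the `analysis/` scripts run the fuller grids.

# Limitations

Beyond the magnitude shortfall discussed above: no centre-of-pressure or
foot–ground contact model (the tilt axis is pinned at the ankle), no
mediolateral dynamics, no tendon compliance, no sensory-fusion state
estimation (the delay is compensated with the exact internal model, a
best-case assumption), and certainty-equivalent planning — the
controller never reasons about its own noise. The experimental
quantities tied to human recordings (cross-subject $R^2$, absolute GC
peak latencies, the measured cue-start distribution) are emulated by the
synthetic generator's defaults, not reproduced from data.
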