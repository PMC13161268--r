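# posturempc

Why would a standing person who knows the floor is about to tilt
backward lean *forward* in advance — and do it while activating the
gastrocnemius (GC), a muscle whose ankle torque points backward?
`posturempc` is an R package for studying this anticipatory postural
adjustment as the outcome of predictive optimal control. It couples

* a **stochastic musculoskeletal plant**: a sagittal-plane two-link
  (ankle + hip) inverted pendulum on a tilting floor, driven by four
  Hill-type muscles (TA, GC, IL, GM) with passive joint stiffness and
  Gaussian joint-torque noise, integrated by Euler–Maruyama at 1000 Hz;
* a **model predictive controller** with disturbance preview: every
  0.1 s it compensates a 150-ms sensory delay through its internal
  model, then minimises
  `J = Σ_Np [(x_COM − x_ref)² + (w_u u)² + (w_δu δu)²]`
  over Nm = 2 moves (Np = 30 steps, a 3-s horizon; COM error in metres;
  box bounds; the signed hip channel drives IL or GM, never both),
  knowing the scheduled floor-tilt trajectory from the cue time onward;
* the matching **measurement pipeline** used on motion-capture/EMG
  recordings: whole-body COM from sagittal markers via segment weight
  ratios, zero-phase Butterworth filtering, five-point differentiation,
  EMG envelopes in %MVC, cue-period (CS–FS) metrics, pooled t-tests,
  cue × stage ANOVAs, OLS regression with confidence bands, COM phase
  portraits, and tilt-response peak latency;
* a **synthetic marker/EMG generator** with known ground truth, so
  every analysis stage is testable without any recorded data.

The default trial is the study protocol: 20 s of standing, a 4° floor
tilt between 15 and 16 s, the tilt previewed from 13 s (the simulated
cue), COM target 61 mm anterior of the ankle, weights
`w_u = 0.01`, `w_δu = 1`, torque noise 0.33 N·m.

## Worked example

```r
library(posturempc)

scn <- scenario()                      # baseline protocol
trials <- run_cohort(scn, n = 20, base_seed = 1)
met <- do.call(rbind, lapply(trials, function(tr) {
  m <- cue_metrics(tr)                 # CS = 13 s, FS = 15 s
  data.frame(delta_com = m$delta_com, slope_GC = m$slope_GC,
             slope_TA = m$slope_TA, com_cs = m$com_cs, com_fs = m$com_fs)
}))
mean(met$delta_com); mean(met$slope_GC)
student_t(met$com_cs, met$com_fs)
regression_with_ci(met$delta_com, met$slope_GC)$r_squared
```

On this cohort the run prints (see `analysis/01_baseline.R`):

```
Baseline cohort (n = 20):
  mean CS->FS COM shift: 10.8 mm (sd 2.3)
  mean GC slope: 1.15 %/s, mean |TA slope|: 0.069 %/s
  COM CS vs FS: t = -18.60, df = 38, p = 1.12e-20
  GC slope ~ COM shift: R^2 = 0.54, p = 0.000247
```

Reading: after the cue the COM drifts forward (10.8 mm here; the
reference experiments and simulations report 20–30 mm — see the
methods vignette for why this implementation lands lower), the shift is
carried by rising GC activity while TA stays silent (|TA slope| ≈ 6% of
the GC slope), the CS-vs-FS difference is overwhelming at df = 38, and
trials that drift further forward ramp GC harder (R² = 0.54) — the
drop-and-catch use of gravity that predictive optimisation discovers.

The numbered scripts under `analysis/` run the full protocols: the
baseline cohort, the input-weight sweep (energy efficiency), the
COM-target sweep (initial-posture invariance), the tilt-magnitude sweep
(disturbance scaling), the long-latency-reflex extension, and the
synthetic-cohort validation of the statistics pipeline. Each writes its
tables under `results/`.

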