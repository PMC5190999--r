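---
title: "EMG- and IMU-driven modelling of elbow muscle forces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG- and IMU-driven modelling of elbow muscle forces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmskit)
```

## The problem

Surface EMG tells a clinician which superficial muscles are active but not
how much force they produce; motion capture tells how the limb moves but not
why. An EMG-driven neuromusculoskeletal (NMS) model couples the two: muscle
excitations derived from EMG drive activation dynamics and a Hill-type
muscle model whose forces, multiplied by their moment arms, must add up to
the joint moment that rigid-body mechanics demands. When they do, the
individual muscle forces in the chain are a physiologically constrained
estimate — the quantity of interest for personalized neurorehabilitation.

The catch is that surface EMG is an unreliable amplitude meter: cross-talk,
electrode placement and uncertain maximum-voluntary-contraction (MVC)
normalization distort each channel by tens of percent, and deep muscles are
not measurable at all. `nmskit` therefore implements a *hybrid* pipeline:
after ordinary EMG-driven calibration, the simulation stage is allowed to
adjust each muscle's excitation within a relative tolerance `Th` so that the
estimated joint moment tracks the experimental one, while the temporal
pattern of the EMG is preserved. Muscle-synergy analysis then verifies that
the adjustment did not invent a new neural control strategy.

## Joint angle from a single IMU

One sensor on the forearm suffices for the single sagittal-plane degree of
freedom of elbow flexion–extension. The state is $(\theta, \dot\theta,
\ddot\theta)$ with $\theta$ the angle between the sensor Y axis and gravity
(0 = forearm hanging, flexion positive). The process model is the
continuous Wiener-process-acceleration (CWPA) model — angular acceleration
is a random walk driven by white jerk of intensity `q` — discretized with
the standard $A$ and $Q$ matrices. The measurement model combines gravity
with the tangential ($\ddot\theta l$) and centripetal ($\dot\theta^2 l$)
accelerations at the sensor's lever arm $l$ plus the gyroscope rate, and an
extended Kalman filter handles its nonlinearity.

Tunable parameters, with defaults:

* `l = 0.15` m — elbow-to-sensor distance; measured per subject in practice.
* `q = 10` (rad/s³)²·s — chosen so the filter comfortably tracks the peak
  jerk of a slow voluntary movement (about 5 rad/s³ for the 5.8 s trial)
  without amplifying noise.
* `R = diag(0.2², 0.2², 0.02²)` — accelerometer noise 0.2 m/s², gyroscope
  noise 0.02 rad/s, typical for consumer MEMS parts.
* Initialization: trials start at rest, so $\theta_0 = \mathrm{atan2}(-a_x,
  -a_y)$ from the first accelerometer sample with zero rates and
  `P0 = diag(0.1, 0.1, 1)`.

The covariance is re-symmetrized after every update; this is cheap numerical
hygiene that keeps long runs positive semidefinite. Multi-DOF motion,
magnetometers and quaternion attitude are out of scope: the sensor's X/Y
plane must stay in the sagittal plane.

## From EMG to activation

Raw EMG is high-pass filtered at 30 Hz, full-wave rectified and low-pass
filtered at 6 Hz, all with zero-phase 4th-order Butterworth filters
(forward–backward application, reflect-padded at three filter lengths, so
burst timing is not lagged), then normalized by the MVC envelope peak and
clipped to $[0,1]$. Clipping events are counted and reported because true
MVC maxima are themselves uncertain. The envelope is decimated from 1000 Hz
to the 50 Hz working rate — safe because its content is below 6 Hz. Three
channels are measured (BIClong, BRD, TRIlat); the neural map assigns
BICshort and BRA the BIClong excitation and TRIlong/TRImed the TRIlat
excitation, the standard shared-innervation simplification for muscles that
cannot be measured non-invasively.

Activation dynamics is the second-order recursive filter
$u(t) = \alpha e(t-d) - (C_1+C_2)u(t-1) - C_1 C_2 u(t-2)$ followed by the
exponential shaping $a = (e^{Au}-1)/(e^A-1)$, $A \in [-3, 0)$ with $A \to 0$
the linear limit. Two constraints are imposed that the recursion needs to be
physiological: the poles $-C_1, -C_2$ must lie in the unit circle
($|C_i| < 1$), and the DC gain must be one so a sustained full excitation
produces full activation. The exact unit-gain condition for this recursion
is $\alpha = (1+C_1)(1+C_2)$, so `alpha` is derived, never free. The
electromechanical delay `d` is bounded by 0.1 s and lives on the 50 Hz
sample grid. Each muscle stores its own parameters; calibration ties them
per muscle group (flexors/extensors) to keep the single-moment-channel
problem identifiable.

## Musculotendon mechanics

Muscle kinematics are polynomials in the elbow angle over $[0, 2.4]$ rad
(no extrapolation). The moment-arm polynomial is primary; the MTU-length
polynomial is its exact antiderivative ($MA = -\,d\ell_{MT}/d\theta$ holds
analytically), anchored so the normalized fiber length is 1 at 1 rad —
placing the ascending-limb-to-plateau region in mid-range, with mild passive
stretch near full extension. The packaged seven-muscle parameter set
(`default_model()`, also shipped as `inst/extdata/elbow_model.yaml`) uses
literature-scale approximate values for maximum isometric forces, optimal
fiber lengths and moment-arm magnitudes; it is a *generic* starting model
meant to be calibrated, not an anatomical measurement, and absolute force
magnitudes from it should not be read as subject-specific truth.

The tendon is rigid: the fiber absorbs all MTU length change under the
constant-thickness pennation model $\ell_m \sin\varphi = \ell_0
\sin\varphi_0$. Force is
$F = F_{max}(f_a f_v a + f_p + d_m \tilde v)\cos\varphi$, floored at zero
(muscles cannot push), with a Gaussian active force–length curve
($\gamma = 0.45$), exponential passive curve (zero below optimal length),
and a Hill hyperbola force–velocity curve ($v_{max} = 10\,\ell_0$/s,
curvature 0.25) joined $C^1$-continuously to an eccentric plateau at 1.4.
The experimental joint moment comes from single-DOF forearm inverse
dynamics, $\tau = I\ddot\theta + m g l_{com}\sin\theta$, with
Savitzky–Golay differentiation (window 11, order 3) and anthropometric
segment defaults (2.2% body mass, center of mass at 68.2% of forearm
length) replacing full-body scaling tools.

## Calibration

Calibration minimizes the RMSE between experimental and estimated moment
over ten group-level parameters: $A, C_1, C_2, d$ and an $F_{max}$ scale
per group, within conventional bounds ($A \in [-3, -0.001]$, $|C_i| < 0.9$,
$d \in [0, 0.1]$ s, scale $\in [0.5, 1.5]$). The optimizer is a seeded,
bounded simulated annealer: initial temperature from the spread of 50
random probes, geometric cooling (factor 0.8, 25 moves per stage), mostly
single-coordinate moves whose width shrinks with temperature, and delay
proposals snapped to the sample grid. Because the objective is a residual
sum of squares that is smooth in the eight continuous parameters but
piecewise-constant in the two delays, the cold end of the schedule is a
quench in the style of modern annealing optimizers: every delay-grid cell
is probed with a short bounded Levenberg–Marquardt polish, the best cells
are polished to convergence, and a mid-bounds restart guards against a
continuous local minimum. Everything, probes included, counts against the
evaluation budget (default 5000), and runs are deterministic given the
seed. Invalid parameter vectors receive a finite penalty (10⁶) rather than
an error so the search space stays box-shaped.

On clean synthetic trials this recovers group force scales essentially
exactly; on distorted excitations it finds the best group-level compromise,
which is precisely the residual the excitation adjustment exists to absorb.

## Excitation adjustment and the tolerance Th

At each 20 ms step the simulation solves

$$\min_{\hat e} |\tau - \hat\tau(\hat e)| \quad \text{s.t.}\quad
\frac{|e_i - \hat e_i|}{\max(e_i, 0.01)} < Th,$$

where $\hat\tau$ is evaluated through the full activation→force→moment
chain with the filter memory carried forward on the *adjusted* inputs (the
self-consistent reading of the simulation flow; the alternative of keeping
original-history filters would make the reported moment inconsistent with
the reported excitations). The floor 0.01 in the denominator gives
near-silent muscles a small absolute adjustment band, without which the
constraint is undefined at $e_i = 0$. The optimization is solved per time
step — the constraint is pointwise, and a trajectory-wide solve is out of
scope.

The solver exploits structure instead of a generic optimizer: at fixed
fiber state the estimated moment is monotone in every excitation
(increasing for flexors, decreasing for extensors), so the constrained
optimum lies on the segment from the unadjusted point towards the
moment-raising or moment-lowering corner of the box, and bisection finds
it. When the target is reachable the returned point is the *closest*
attaining point on that segment (smallest adjustment, which also makes the
result deterministic); when it is not, the corner is optimal. The solver is
validated against dense grid searches in the tests. Because the boxes nest
and the segment direction is identical across Th, moment error is
nonincreasing and excitation deviation nondecreasing in Th; both trends are
asserted as properties.

`tune_th()` grows Th from 0.1 in steps of 0.1 (capped at 0.9, inside the
open interval the constraint allows) and stops at the first Th meeting
moment NRMSD ≤ 0.04 and R² ≥ 0.95 — deliberately strict bounds, an order
tighter than the conventional acceptability range for joint-moment
estimation. If no Th qualifies, the best result is returned flagged
`converged = FALSE`.

Here NRMSD is the RMS difference divided by the *combined* range of the two
series (maximum over both minus minimum over both) — the symmetric reading
of the definition — and R² is $1 - SS_{res}/SS_{tot}$ about the reference
mean, which can be negative for poor fits; the squared-correlation reading
was rejected because it ignores amplitude errors, which are exactly what
moment tracking must penalize.

## Synergy validation

Non-negative matrix factorization (multiplicative Frobenius updates, 500
iterations, tolerance 1e-8, best of 5 seeded restarts) factorizes the
7 × time excitation matrix into `k = 2` synergies — one flexion, one
extension pattern, the natural structure of this movement — with unit-norm
synergy vectors and the scale folded into the recruitment weights.
Similarity between the measured-excitation and adjusted-excitation synergy
sets is the scalar product of matched unit columns (exhaustive matching for
`k ≤ 5`). Only the synergy basis `W` enters the similarity, per the
convention of the synergy literature; the recruitment curves are not
compared.

## The synthetic study conditions

`generate_trial()` emulates the experimental protocol: a 5.8 s minimum-jerk
flexion from 10° to 130° and back (minimum-jerk because slow voluntary
movements are smooth with zero boundary velocity and acceleration), IMU
readings synthesized through the same measurement model with Gaussian noise
(0.2 m/s², 0.02 rad/s), and Gaussian-bell excitation bursts — flexors
peaking at mid-flexion, extensors at mid-extension, peaks between 0.2 and
0.6 on a 0.02 tonic baseline. "Measured" excitations are the true ones
distorted by a per-muscle constant amplitude gain $1 + U(-p, p)$ with
$p = 0.2$ plus additive noise ($\sigma = 0.02$) — the two dominant sEMG
uncertainty sources (MVC normalization error and cross-talk). The trial's
experimental moment is the forward-model moment of the *true* excitations,
guaranteeing an internally consistent ground truth; a
noisy-inverse-dynamics route exists separately
(`inverse_dynamics()`, `consistent_excitations()`) and closes with the
forward chain to NRMSD < 0.02.

What these trials do **not** emulate: raw EMG waveforms (excitations are
generated post-envelope), time-varying gain drift, fatigue, co-contraction
strategies beyond the tonic baseline, movement-artifact transients, or any
multi-DOF kinematics. Passing the synthetic suite therefore demonstrates
the pipeline's internal consistency and its robustness to amplitude-type
EMG uncertainty — not clinical validity on recorded patients.

## Numerical choices and degenerate inputs

* All modelling runs at 50 Hz; EMG is decimated after enveloping.
* Angle estimates are clamped to the kinematic polynomial range
  $[0, 2.4]$ rad before entering muscle kinematics; the polynomials are
  never extrapolated.
* The activation recursion is applied as an exact linear filter and clipped
  to $[0,1]$ afterwards; with unit DC gain and bounded excitations the clip
  is inactive in normal operation.
* Zero combined range (NRMSD) and constant references (R²) raise errors
  rather than returning NaN.
* Bisection in the adjustment solver runs to a moment tolerance of 1e-10
  N·m or 60 halvings; ties are broken towards the smallest adjustment.
* Problem sizes used in the validation suite: 291-sample trials (5.8 s at
  50 Hz), 20-trial angle-estimation batches, 5000-evaluation calibrations.

## Known limitations

One degree of freedom only; generic (uncalibrated) anatomical polynomials;
rigid tendon; group-tied calibration parameters; per-sample (greedy)
adjustment rather than a horizon-wide optimal control; synergy count fixed
rather than selected by variance accounted for. Each is the simplest choice
consistent with the method's purpose, and each is an explicit extension
point.
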