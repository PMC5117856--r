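---
title: "Effort-optimal planning of arm movements under gravity: models, measures, and recovery of the internal gravity estimate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort-optimal planning of arm movements under gravity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armplan)
```

## The scientific question

When the arm rotates about the shoulder in a vertical plane, gravity does
positive work on downward movements and negative work on upward ones. Two
planning strategies make opposite predictions about how movement
kinematics should depend on direction. Under a *compensation* strategy the
nervous system uses its internal model of gravity to cancel gravitational
torque and produce the same (symmetric) velocity profile in every
direction. Under an *effort-optimization* strategy the internal model is
used to *exploit* gravity: letting it help accelerate downward movements
and decelerate upward ones, which skews the velocity profile in a
direction-dependent way.

The discriminating statistic is the **symmetry ratio** (SR): acceleration
time divided by total movement time of the (single-peaked) speed profile.
SR = 0.5 means a temporally symmetric profile; SR below/above 0.5 means
the peak occurs early/late. This package implements, end to end:

* the single-degree-of-freedom arm model and its gravity torque;
* four optimal-control models of a rest-to-rest 45° shoulder rotation
  (Smooth-Effort, minimum jerk, minimum torque-change, and open-loop
  minimum variance with signal-dependent noise, with and without muscle
  dynamics);
* the motion-capture analysis pipeline (zero-phase Butterworth filtering,
  5%-of-peak movement detection, per-trial features);
* a synthetic marker-recording generator standing in for the human
  recordings; and
* the adaptation analysis that recovers the planner's internal gravity
  value from the directional SR difference.

## Arm model

The arm is a single rigid segment rotating about the shoulder. With
shoulder angle $\theta$ (zero at the horizontal initial posture,
increasing toward the target) in a plane inclined by $\gamma$ relative to
horizontal ($\gamma = -90^\circ$ straight up, $+90^\circ$ straight down),
the gravity torque projected on the plane of motion is

$$GT(\theta, \gamma) = m\,g\,l\,\cos\theta\,\sin\gamma,$$

positive when it acts toward the target, and its work over the movement
is $WGT = \int GT\, d\theta = m g l \sin\gamma\,[\sin\theta]$, evaluated
in closed form. The net muscle torque follows from the equation of motion

$$\tau = I\ddot\theta + B\dot\theta - GT(\theta,\gamma),$$

with inertia $I$, viscous friction $B = 0.87\;\mathrm{N\,m\,s/rad}$, and
the sign of $GT$ chosen so that an assisting gravity torque *reduces* the
muscle torque requirement (static postures then need
$\tau = -GT$, e.g. a positive torque to hold the arm up).

Anthropometry uses whole-arm segment coefficients from a standard table:
segment mass = 0.050 × body mass, centre of mass at 0.530 × arm length
from the shoulder, and radius of gyration about the shoulder of
0.645 × arm length ($I = m (0.645 L)^2$). All three are overridable in
`anthropometrics_from_body()`. For the nominal 70 kg, 0.70 m subject used
throughout: $m = 3.5$ kg, $l = 0.371$ m, $I = 0.714$ kg m².

## The four cost models

All models solve a rest-to-rest movement of fixed amplitude (45°) and
duration (T = 0.40 s), with zero boundary velocities and, for the
torque-based models, static boundary torque (zero boundary acceleration).

**Smooth-Effort** minimizes the hybrid cost

$$C = \int_0^T |\tau\dot\theta|\,dt \;+\; \alpha \int_0^T \dddot\theta^2\,dt,
\qquad \alpha = 7\times10^{-5},$$

the absolute work of the muscle torque plus a squared-jerk smoothness
term. The absolute value is what creates direction tuning: when gravity
can do part of the work, the cheapest profile shifts its peak so that the
muscle is briefly silent (τ ≈ 0) around peak velocity.

**Minimum jerk** has the classical quintic closed form, independent of
dynamics and direction, with SR exactly 0.5 and peak speed
$(15/8)\,A/T$.

**Minimum torque-change** minimizes $\int (d\tau/dt)^2 dt$. Without
gravity and friction, $\tau \propto \ddot\theta$ and the solution
coincides with minimum jerk (a useful exact cross-check).

**Minimum variance** linearizes the dynamics by freezing the gravity
torque at its initial-posture value ($k = mgl\cos\theta_0 \sin\gamma$),
discretizes with $\Delta t = 10$ ms, and propagates the mean and
covariance of the state under multiplicative control noise
($w_t \sim N(0, \sigma u_t^2)$, $\sigma = 0.2$). The objective is the
summed positional variance over a post-movement stabilization window of
$R$ steps ($R$ = movement steps by default), subject to the mean reaching
and holding the static target. Because the positional variance is a
positively weighted sum of squared controls and the target condition is
linear in the controls, the problem is an equality-constrained diagonal
quadratic program solved exactly through its KKT system. A corollary
worth noting: under this linearization the gravity level only shifts the
torque state, so the optimal angle profile — and hence SR — is *exactly*
direction-invariant.

The muscle-dynamics variant represents agonist and antagonist muscles as
first-order filters (time constant 0.05 s) with torque
$\rho(a_{ag} - a_{ant})$, $\rho = 60$ N m, and motoneuron inputs bounded
in $[0,1]$. Pinning the terminal *activations* is infeasible (first-order
activations decay geometrically and can never reach an exact value and
stop), so the reach-and-hold contract is imposed on what it physically
means: mean position at the target at movement end and zero mean velocity
at every step of the stabilization window, with hold-phase inputs as free
decision variables. The resulting convex bound-constrained QP is solved
with the Goldfarb–Idnani dual active-set method (`quadprog`).

### Numerical method for the trajectory optimizations

For the Smooth-Effort and torque-change costs the control is the torque
rate and the dynamics define τ explicitly from θ and its derivatives, so
the optimal-control problem reduces to an unconstrained minimization over
smooth angle trajectories. The angle is parameterized as the minimum-jerk
quintic plus a polynomial perturbation

$$\theta(s) = \theta_{mj}(s) + \sum_{k=0}^{K-1} c_k\, s^3(1-s)^3 P_k(2s-1),
\qquad s = t/T,$$

with shifted Legendre polynomials $P_k$. The envelope $s^3(1-s)^3$ makes
every candidate satisfy the position, velocity and acceleration boundary
conditions exactly, and the dynamics hold identically at every point —
there are no collocation constraints to enforce. Cost integrals are
evaluated by Gauss–Legendre quadrature ($n_{quad} = 120$ nodes) and
minimized by BFGS with analytic gradients from $K = 14$ basis functions.
The nonsmooth $|x|$ in the effort term is replaced by
$\sqrt{x^2+\varepsilon^2}$ with a continuation
$\varepsilon: 10^{-2} \to 10^{-4} \to 10^{-6}$ (W); tests verify that
halving the final ε moves SR by far less than 0.001, and that doubling
both $K$ and $n_{quad}$ changes the cost by <1% and SR by <0.005.
Solutions are verified to be initialization-independent (minimum-jerk
start vs a projected cosine ramp). An independent trapezoidal
state-space collocation implementation was used during development to
cross-check the optimizer; both agree on SR to better than 0.006 at all
tested directions.

### Sensitivity of the symmetry ratio near the strategy boundary

Two genuine, and initially surprising, properties of the Smooth-Effort
model at the reference parameter values (α = 7e-5, B = 0.87, T = 0.40 s) deserve documentation because
they shape what the package can and cannot reproduce.

First, the predicted SR is **not monotone in the gravity level**. The
directional asymmetry (SR_down − SR_up for vertical movements) rises
steeply up to an internal gravity of roughly 3–5 m/s², then *decreases*
again toward zero as g approaches twice Earth gravity. The reason is
mechanical: once the anti-gravity torque is so large that the muscle
torque never changes sign during the movement, the absolute-work term
$\int|\tau\dot\theta|dt$ becomes path-independent (it equals the net work
fixed by the endpoints), leaving the jerk term to symmetrize the profile.

Second, along the direction axis at 1g the model's tuning curve has a
sharp knee near $|\gamma| \approx 15^\circ$, where the optimal strategy
switches to the gravity-exploiting profile. Around the knee the optimal
speed profiles are flat-topped (the muscle is silent over a window), so
the time-to-peak statistic moves quickly even though the underlying
trajectory changes smoothly; warm-started continuation in γ finds no
hysteresis and an independent solver reproduces the same curve, so this
is a property of the optimum, not of the optimizer. A practical
consequence is that the correlation between model SR and WGT across the
17 directions evaluates to about 0.87 for this implementation at the
reference parameter set — high, but lower than ideal linearity; the
tuning curve is steeper than the sine-shaped WGT curve it is regressed
against. Users exploring other parameter regimes can use
`predict_sr_curve()` directly.

## Kinematic pipeline

The feature pipeline mirrors a standard optoelectronic recording setup:
five markers (shoulder, elbow, wrist, hand, index fingertip) sampled at
120 Hz. Marker positions are low-pass filtered with a 5th-order
Butterworth at 10 Hz applied forward–backward — zero phase, so onset and
offset times are not lag-shifted; any constant lag would bias SR. The
fingertip tangential speed is the norm of the central-difference
derivative of the filtered position. Movement onset/offset are the last
up-crossing before, and first down-crossing after, the speed peak at 5%
of peak speed; crossing times are linearly interpolated between samples
and the peak time is refined on a spline-upsampled profile (the filtered
speed is band-limited far below Nyquist, so this recovers the continuous
profile; at 120 Hz and 0.4 s movements, whole-sample resolution would be
about 1/48 of the movement — too coarse against the 0.01-level
contracts). Profiles with more than one local maximum above 20% of the
global peak are rejected, mirroring the single-peak inclusion criterion.
SR is computed from the interpolated landmark times; the final angular
error is the fingertip elevation in the movement plane, averaged over the
settled posture at the end of the trial, minus the 45° target (positive =
overshoot). Per subject × direction cell, the systematic error is the
mean signed error and the variable error the *sample* standard deviation
(the n−1 convention; the source analyses do not state which convention
they used).

## Synthetic data generator

`generate_trial()` embeds a single-DOF angle time course as rigid motion
of the five markers on a sphere of radius arm-length about the shoulder,
in the plane of inclination γ, samples at 120 Hz with 0.3 s of rest
padding at each end, and adds white Gaussian marker noise (SD 0.5 mm by
default). Trial durations are drawn from a truncated normal
(0.40 ± 0.01 s). Two profile modes exist:

* **model_driven** — the angle course is the Smooth-Effort optimum at the
  condition's *internal* gravity value (solved once per subject ×
  direction × g at the nominal duration and uniformly time-rescaled for
  per-trial duration jitter; SR is invariant to uniform time rescaling).
  The generator distinguishes the planner's internal gravity from the
  environmental gravity, so partially adapted planning in weightlessness
  is representable.
* **profile_driven** — an analytic beta-density-shaped speed profile
  whose parameter is root-found so that the *pipeline-measured* SR
  (120 Hz sampling, 10 Hz zero-phase filter, 5% thresholds) equals the
  requested target. Calibrating through the measurement definition
  matters: the filter symmetrizes skewed bells by about 0.01 at SR 0.35
  or 0.65, which would otherwise eat the whole round-trip error budget.

Experiment designs: the 1g session (default 15 subjects × 17 directions
× 12 trials = 3060 trials, randomized within subject, per-subject
anthropometrics drawn uniformly from 55–90 kg body mass and 0.60–0.80 m
arm length) and the parabolic-flight session (up/down movements across a
1g baseline and parabolas P1–P5, with the internal gravity following a
configurable schedule, default 9.81, 7.5, 5.5, 3.5, 2.0, 1.0 m/s² to
emulate progressive adaptation). What the generator does *not* emulate:
soft-tissue marker artifacts, occlusions, multi-joint leakage,
trial-to-trial amplitude variability beyond duration jitter, and any
feedback corrections — so green round-trip tests validate the pipeline's
internal consistency, not its robustness to every artifact of real
recordings.

## Recovering the internal gravity estimate

`fit_internal_g()` finds the gravity value g (bounded to ±2 × 9.81) whose
model-predicted SR difference (down − up, two Smooth-Effort solves at
gravity g) best matches an observed difference. Because the forward map
g → SR-difference is two-branched (see above), an observed difference
generally has two preimages; the fit therefore keeps the contract of a
bounded scalar search but resolves near-ties (objective within 1e-4) by
proximity to a prior value — 9.81 by default, the estimate a person
walks in with. `adaptation_timecourse()` fits the six phases
sequentially, initializing each phase at the previous fit and bounding it
above by that fit (a monotone-adaptation constraint: the internal
estimate is assumed not to *increase* during sustained weightlessness).
Under this scheme the default synthetic schedule is recovered with median
absolute error well under 1 m/s²; the one residual failure mode is the
flat top of the forward curve (g between roughly 3.5 and 6.5 maps to
nearly identical differences, so fits in that band can be off by up to
~2–3 m/s² without any detectable change in the data). An *increasing*
gravity schedule would not be identifiable from SR differences alone;
that limitation is intrinsic to fitting only the directional difference.
Candidate g values are quantized to 0.05 m/s² and all trajectory solves
are memoized package-wide, which is what makes replicated recovery
studies tractable.

## Problem sizes and determinism

The test suite and the acceptance script run at these scales: 17
directions per tuning curve; variance models at Δt = 10 ms (40 movement +
40 hold steps); recovery studies with 20 replicates of 2 subjects × 8
trials per phase × direction (≈16 trials per cell, the scale of the
parabolic-flight protocol). All randomness flows from explicit seeds
through a private RNG so generation never disturbs the caller's RNG
state; identical seeds give bit-identical recordings and features.

## Known limitations

* The Smooth-Effort SR–WGT correlation across directions is ≈0.87 at the
  reference parameter set in this implementation (see the sensitivity
  section); the tuning curve is sigmoid but steeper than a sine in WGT.
* The minimum-variance models are open-loop (no feedback control), as
  specified; they predict direction-invariant SR by construction
  (3-state exactly; muscle variant to within 0.01 at defaults).
* The internal-g fit assumes monotone adaptation and an Earth-gravity
  prior; both are explicit, documented estimator choices.
* Multi-segment dynamics, interaction torques and C3D motion-capture
  formats are out of scope.
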