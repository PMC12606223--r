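---
title: "Joint-level force-velocity analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-level force-velocity analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointfv)
```

## The problem this package addresses

Musculoskeletal simulations emit many parallel time series per muscle
(activation, velocity, force, torque), and the functional role of a joint -
is it powering the movement, braking it, or stiffening against
disturbance? - is hard to read off stacked line plots. `jointfv`
implements a joint-level force-velocity (joint-FV) representation for an
antagonistic muscle pair: at every instant the joint's state is a point
(normalized joint velocity, normalized net torque) that lives on an
*instantaneous joint-fv curve*, and a whole movement becomes a single
trajectory through a four-quadrant phase plane. The package contains the
analytical layer (curves, quadrants, slopes, trajectory metrics), a planar
three-joint muscle-driven reaching simulator to generate data, and the
plotting/animation layer.

## Muscle model

Each muscle is a torque-level Hill-type actuator with a piecewise
force-velocity gain against normalized velocity $\tilde v$ (positive =
shortening):

$$
FV(\tilde v) =
\begin{cases}
\dfrac{1 - \tilde v}{1 + d_1 \tilde v}, & \tilde v > 0\\[1ex]
d_2 - (d_2 - 1)\dfrac{1 + \tilde v}{1 - d_3 \tilde v}, & \tilde v \le 0
\end{cases}
$$

with shape constants $d_1 = 4$, $d_2 = 1.8$, $d_3 = 30.24$ by default.
Both branches equal 1 at $\tilde v = 0$; the shortening branch reaches 0
at $\tilde v = 1$ and the lengthening branch approaches the eccentric
plateau $d_2$. Velocities are normalized per muscle by
$\dot\theta_{max} = v_{max}/r$, where $r$ is a constant moment arm; torque
is $a\,F_{max}\,r\,FV(\tilde v)$ with activation $a \in [0,1]$.

Deliberate simplifications, each with a configuration hook:

* **No force-length gain.** Velocity effects are treated as dominant for
  fast reaching; `muscle_torque()` accepts an optional `fl_gain`
  multiplier if a length dependence is wanted later.
* **Constant, equal moment arms within a pair.** The antagonist simply
  sees the joint velocity with opposite sign.
* **Excitation-activation coupling** is a cascade of three identical
  first-order stages. The time constant is not something we could take
  from a published table for this abstract muscle, so we chose
  $\tau = 20$ ms per stage (configurable), giving a realistic
  tens-of-milliseconds rise and - the property that matters downstream -
  zero initial slope after an excitation step. Deactivation uses the same
  constants by default; `activation_state(tau_fall=)` provides the
  asymmetry hook.

## The joint-fv curve and space

For an agonist/antagonist pair with activations $a_{ag}, a_{ant}$ and
strength ratio $b$ (maximum isometric antagonist torque over agonist
torque, 1 for an identical pair):

$$
fv_{joint}(\tilde v) \;=\; a_{ag}\,FV_{ag}(\tilde v)\;-\;b\,a_{ant}\,FV_{ant}(-\tilde v)
$$

The *ceiling* (antagonist silent) and *floor* (agonist silent) curves
bound the joint-fv space the pair can reach without changing which muscle
dominates; the current curve always lies between them and crosses the
torque axis at the net activation $a_{net} = a_{ag} - b\,a_{ant}$.
Co-activation is reported as $\min(a_{ag},\, b\,a_{ant})$ - the level of
activation simultaneously present in both muscles, weighted so a weak
antagonist cannot "co-contract" more than its torque-equivalent share.
This is the literal reading of simultaneous activation and reduces to the
obvious values at the extremes (0 with a silent antagonist, full at equal
weighted activation).

Because both one-sided derivatives of $FV$ are negative, the antagonist's
reflected curve *adds* steepness:
$fv_{joint}'(0^+) = a_{ag}FV'(0^+) + b\,a_{ant}FV'(0^-)$, i.e.
$-5$ for a lone fully active agonist and $-29.992$ under full
co-contraction with default constants. The slope is the intrinsic damping
proxy: the steeper the local curve, the larger the torque change opposing
any velocity change, which is the mechanism behind the fast rebound from
hand-force perturbations in the simulations.

Quadrants are labelled with velocity positive in the agonist's shortening
direction: I = agonist-direction motion with positive net torque (power
generation), IV = same motion braked by the antagonist, III/II mirror
those for antagonist-direction motion. Points within `1e-3` of either
axis are labelled `on-axis`; this tolerance exists purely to stop
noise-driven quadrant flicker in run-length-encoded sequences, and the
classification is invariant under any uniform rescaling of the torque
axis.

The **agonist is a task role, not an anatomical label**: the muscle with
the larger positive mechanical power integral (torque times signed joint
velocity) over the first 0.05 s of the movement. With constant moment
arms this torque-level power is proportional to fibre power. If neither
muscle delivers positive early power the choice is genuinely ambiguous
and `select_agonist()` refuses with a diagnostic rather than guessing.

## The reaching simulator

The arm is a horizontal-plane (gravity-free) chain of three rigid
segments with hinge joints at shoulder, elbow and wrist, each driven by
one antagonistic pair. The equations of motion
$M(q)\ddot q + C(q,\dot q)\dot q = \tau + J^\top F_{ext}$ are assembled
from centre-of-mass Jacobians ($M$) and the Christoffel symbols of $M$
($C$), which guarantees the standard skew-symmetry of $\dot M - 2C$ and
makes the interaction (centrifugal/Coriolis/Euler) torques explicit. The
test suite checks the implementation against an independent Lagrangian
oracle built from complex-step kinematics and numerical derivatives of
the kinetic energy.

Coordinate convention: the world frame has +x to the subject's right and
+y to the front, anticlockwise angles positive, shoulder at the origin -
a right arm seen from above. The committed target coordinates (forward
`(0.05, 0.50)` m, sideways `(0.45, 0.15)` m, cross-body `(-0.30, 0.35)` m)
are meaningful in exactly this frame. Joint angles are measured relative
to the parent segment, so proximal motion drags distal joints - the
source of the interaction torques the joint-FV trajectories expose.

Default anthropometry (all configurable): upper arm 0.30 m / 2.0 kg,
forearm 0.30 m / 1.5 kg, hand 0.15 m / 0.5 kg, centres of mass
mid-segment, slender-rod inertias. Muscle strengths: shoulder
600 N, elbow 400 N, wrist 150 N with moment arms of 5/5/3 cm and
$\dot\theta_{max} = 20$ rad/s at every joint - plausible human-scale
values for an abstract arm of this size.

**Initial posture.** The default start is shoulder 10°, elbow 120°,
wrist 0° (hand in front of the chest, ~0.40 m from the shoulder). We
chose this posture, rather than a more extended one, because it is the
configuration from which the committed targets produce the canonical
forward-reach pattern - shoulder flexion with elbow and wrist extension;
from a half-extended start the same forward target would be reached by
the opposite joint-direction pattern, which defeats the purpose of the
packaged conditions. Posture is a per-scenario config entry.

**Control.** The reference is a joint-space minimum-jerk quintic - the
canonical bell-shaped-velocity plan, matching every boundary property a
planned reach needs (zero end velocities, single interior speed peak).
Final joint angles come from closed-form inverse kinematics with a
configured final wrist angle (-0.15 rad, slight extension). The
controller is deliberately primitive: a per-joint PD law on tracking
error mapped to excitations by sign-splitting, so at most one muscle per
joint is *excited* at any instant. All co-contraction in the simulations
is therefore emergent, produced by the lag of the activation cascade -
none is commanded. Gains are committed in the configs (Kp = 60, Kd = 8
per joint, reference time 0.35 s), tuned with the included
`tune_gains()` grid search so the forward reach settles within 1 cm of
the target before 0.5 s; a gain block is part of each scenario file, not
a hidden constant.

**Integration** is fixed-step RK4 at `dt = 1e-4` s, chosen over adaptive
stepping for bit-level reproducibility and a trivially verifiable order:
halving the step shrinks the error ~16-fold, passive swings conserve
kinetic energy to better than one part in 10^6 over a second, and two
runs of the same config are identical. Simulations that leave the
Hill-model's calibrated range (any $|\tilde v| > 1$) warn with the count
of offending evaluations; the committed scenarios, including the
perturbed one, stay inside it. Negative force-velocity gains (shortening
faster than $v_{max}$) are floored at zero in torque generation - muscles
pull or do nothing.

**Perturbation.** A point force at the hand, 100 N directed 90°
anticlockwise from the instantaneous hand velocity (recomputed every
step), switched on 150 ms into the reach. Its duration is modelled as a
10 ms rectangular pulse: a "point force injection" is read as a brief
impulse whose observable signature is a transient torque/torque-rate
spike, and the pulse width is a config field for anyone who prefers a
sustained push. If the hand is at rest during the window the direction
is undefined; the force falls back to a configured fixed direction with
a warning.

## The single-joint toy model

`run_scenario("toy")` produces two time-aligned variants of a 0.5 rad
single-joint movement: the analytic plan (inverse dynamics
$\tau = I\ddot q_{des}$ converted to activations through the FV gain, no
co-contraction, executed open-loop with activations applied directly)
and a PD-tracked run through the full excitation cascade. The plan
reproduces the reference to ~1e-15 rad, confined to quadrants I and IV;
the tracked variant lags, overshoots, and adds the corrective loop
through quadrants III and II - the minimal demonstration that imperfect
execution, not the plan, creates the extra quadrant visits.

## Synthetic fixtures

`generate_fixture()` builds single-joint `sim_result` objects without the
dynamics engine: `single_muscle` (constant agonist activation, bell
velocity - the trajectory must lie exactly on the scaled agonist curve),
`coactivated` (equal activations, symmetric velocity sweep - trajectory
odd-symmetric), and `biphasic_reach` (two velocity humps and tri-phasic
activation bursts, optional seeded noise). They emulate the *shapes* of
real simulation output - smooth bell velocities, burst-like activations -
but none of its dynamics: no interaction torques, no feedback, no
activation lag. Tests that pass on fixtures therefore validate the
analysis and plotting layers, not the simulator; simulator properties
are tested against the oracle and conservation laws.

## Numerical choices and edge cases

* Joint-fv curves are sampled on 401 uniform points over $[-1, 1]$ -
  dense enough to resolve the kink at zero velocity for plotting and
  for finite-difference slope checks.
* `local_slope()` is analytic and one-sided; the side argument matters
  only at the kink.
* Trajectory metrics: shoelace signed area over the implicitly closed
  polygon (negative = clockwise under the joint-FV axis convention),
  run-length-encoded quadrant sequence with on-axis points dropped,
  torque-axis crossing count, and first-to-last closure distance. No
  shape *classifier* is imposed: the circular / tied-loop / fish-like
  categories seen in reaching data are qualitative, so the package
  reports the measurable ingredients and leaves labelling to the user.
* Whether trajectories are normalized per joint (by the agonist's
  $F_{max} r$) is a genuine convention choice; we normalize so that
  simulated trajectories are dimensionally identical to theoretical
  joint-fv curves and can be overlaid on them, which the frame renderer
  asserts at draw time.
* Problem sizes: committed reaches simulate 0.7 s at `dt = 1e-4`
  (7001 samples); the energy-conservation check runs 1 s passively; the
  order check uses coarser steps over 0.2 s. These sizes keep every
  documented property measurable at full resolution.

## Known limitations

Single muscle pair per joint, monoarticular only; no tendon elasticity,
pennation, history dependence or short-range stiffness; torque-level
actuation (no muscle paths or wrapping); joint limits off by default; no
gravity or 3D dynamics. The perturbation facility exposes magnitude,
direction and timing but the packaged conditions deliberately include
only the single committed pulse - systematic perturbation sweeps are out
of scope. Hill-type models are at their weakest for transients, so the
perturbation is kept small enough that muscle speeds never exceed
$v_{max}$ during the committed scenarios.
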