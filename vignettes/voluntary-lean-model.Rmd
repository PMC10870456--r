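---
title: "A neuromechanical model of voluntary lean: simulation, segmentation and gain identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuromechanical model of voluntary lean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leansim)
```

## The problem

In limit-of-stability (LoS) protocols a standing subject leans voluntarily
toward one of eight floor targets while the centre of pressure (COP) is
recorded on a force plate, typically at 80 Hz. The COP trace of one trial
decomposes into five phases: quiet *preparation*, a *planning* delay after
the target lights up (reaction time $t_r$), an *anticipatory postural
adjustment* (APA) — a short COP excursion *away* from the target —
the *reaching* excursion to its maximum, and the *return* to upright.
Parkinson's disease reshapes this trace: the temporal parameters lengthen
(bradykinesia) and the APA shrinks.

`leansim` implements a generative model of such trials, the measurement
side that decomposes a recorded trial into the five phases, an inverse
procedure that identifies two subject-specific control gains from two COP
features, a synthetic-cohort generator with the published group structure,
and the group-level statistics. Everything is exercisable without access
to patient recordings.

## The model

### Plant

The body is a single inverted pendulum about the ankle ("ankle strategy"):

$$J_B\,\ddot\theta = m\,g\,L_{COM}\sin\theta + \tau,$$

with $\theta$ the lean angle from vertical along the task direction, $m$
body mass, $L_{COM}$ the ankle-to-COM height and $J_B$ the moment of
inertia about the ankle. Anthropometry is derived from height and mass by
documented conventions, both overridable: $L_{COM} = 0.5527\,h$ (the
classic COM-height proportion of stature) and the point-mass inertia
$J_B = m L_{COM}^2$. Passive ankle mechanics contribute
$\tau_{AIS} = -(K_A\theta + B_A\dot\theta)$; their magnitudes are not
canonically published, so the defaults scale with the gravitational
toppling stiffness ($K_A = 0.15\,mgL_{COM}$, $B_A = 0.05\,mgL_{COM}$ per
radian) and are deliberately sub-critical: without active control, upright
stance is unstable, which the tests assert.

The emitted measurement is the linearized single-pendulum COP/ZMP
relation

$$\mathrm{COP} = L_{COM}\,\theta - \frac{J_B}{mg}\,\ddot\theta$$

(output in cm). This choice reproduces the two facts any COP output must
have here: statically the COP equals the ground projection of the COM,
and an angular acceleration *toward* the target throws the COP *away*
from it — the mechanical origin of the APA.

### Motor planning

The reference trajectory is a minimum-jerk lean with a bell-shaped
velocity profile,

$$\theta_{ref} = \theta_0 + (\theta_0-\theta_f)\left(A_1\tau^4 - A_2\tau^5 -
A_3\tau^3\right),\qquad \tau = \frac{t - t_r}{t_f},$$

with defaults $A_1 = 15, A_2 = 6, A_3 = 10$ — the unique choice for which
$\theta_{ref}$ runs from $\theta_0$ to $\theta_f$ with zero endpoint
velocity and acceleration. The return is modelled as the mirrored profile
over $t_b$; the derivatives the controllers consume are always analytic,
never numeric. The target angle comes from the LoS geometry
$d = 0.3\,H_{CoM}\tan\theta_{limit}$, with the protocol's standard limit
angles per target, and $\theta_f = \operatorname{atan}(d/H_{CoM})$.
Diagonal targets are handled as a one-degree-of-freedom lean along the
straight line to the target. The ankle-to-COM height used by the target
geometry is identified with $L_{COM}$ throughout.

### Postural control

Torque has three components. A feedback law on the tracking error (gains
per degree, the convention in which the published gains are stated):

$$\tau_{FB} = K_P(\theta_{ref}-\theta) + K_I(\dot\theta_{ref}-\dot\theta),
\qquad K_I = 5\ \mathrm{N\,m/(deg/s)}\ \text{fixed};$$

a feedforward path through the inverse pendulum model applied to the
*planned* trajectory,

$$\tau_{FF} = K_{FF}\left(J_B\,\ddot\theta_{ref} -
m g L_{COM}\,\theta_{ref}\right)$$

(angles in radians internally); and the passive torque $\tau_{AIS}$.
During the APA window $t_r < t < t_r + t_{APA}$ the two active paths are
mixed with the time-varying weight $\alpha = (t-t_r)/t_{APA}$:

$$\tau = \alpha\,\tau_{FF} + (1-\alpha)\,\tau_{FB} + \tau_{AIS},$$

and $\tau = \tau_{FB} + \tau_{AIS}$ afterwards. This printed mixing rule
is feedback at APA onset and feedforward at APA end, which is the
*opposite* of the narrative hand-over it is usually described with
("shifts smoothly from feedforward to feedback"); since the two readings
genuinely conflict, the package implements the printed rule as the
default and offers `blend = "narrative"`, which swaps the weights. Both
are tested. Either way the blend has one torque discontinuity at a window
edge; its consequences are discussed under *Limitations*.

Before target onset the controller regulates about the upright reference
with the same feedback law — the preparation phase is not specified by
the protocol, and quiet regulated stance is the least-assumption choice.

### What the closed loop produces

With feedforward present, the early reference acceleration commands a
torque burst; the body accelerates toward the target while barely
displaced, so the COP swings backward first — an APA whose size grows
with $K_{FF}$ — then the reach proceeds under feedback. Static stability
of the loop requires $(K_P + K_A)$ per radian to exceed $mgL_{COM}$; this
is validated at simulation setup and gain settings below it are reported
as unstable rather than integrated.

## Numerical choices

- Fixed-step classical RK4 at `dt = 1/800 s`, chosen so the 80 Hz
  force-plate output grid is an exact 10-fold subsample of the
  integration grid (an even millisecond step does not divide 1/80 s). The
  reference trajectory is precomputed analytically on the half-step grid
  the RK4 stages read.
- A trial is `prep_s` (default 5 s, the protocol's calibration window) +
  $t_r + t_f$ + optional hold + $t_b$ + `tail_s` (default 3 s, so the
  return settles and the returning phase can be segmented).
- $|\theta| > 45^\circ$ is treated as divergence and raises a typed error
  naming the gains.
- Measurement noise, when enabled, is additive white noise on the emitted
  COP channels only, with a mandatory explicit seed; the model itself is
  deterministic (no process noise), and seeded runs are bit-reproducible.

## Segmentation

The planar trial is projected onto the unit vector toward its target
after centring each channel on its baseline mean (the 5 s preparation
window, configurable). Detection and features follow the trace's
standard reading:

- **APA onset**: first post-onset time the signal exceeds twice the
  baseline SD *opposite* the target, sustained for ≥ 50 ms. The sustain
  requirement is this package's guard against single-sample noise
  crossings. $t_r$ = onset − target onset.
- **APA end**: first return to the baseline mean; $t_{APA}$ and the
  peak-to-peak **APA size** are measured on that window.
- **Reaching**: $t_f$ runs from APA onset to the global toward-target
  maximum; **Lean_max** is that maximum minus baseline.
- **Return**: $t_b$ ends at the first local extremum after the signal
  enters a band of ±10 % of Lean_max around baseline (configurable);
  when the approach is monotone the band entry itself is used and the
  result says so. $t_{total} = t_r + t_f + t_b$ holds by construction.

An optional zero-phase second-order Butterworth low-pass (`filter_hz`) is
available for noisy recordings but is **off by default**: zero-phase
filtering smears the post-onset excursion backwards in time and biases
the threshold-crossing onset early by one to three samples, which is
larger than the one-sample accuracy the noiseless round trip otherwise
achieves. The simulator's output is band-limited by construction and
needs no filtering.

## Gain identification

$K_P$ and $K_{FF}$ are the only free parameters; the temporal plan enters
as measured. Given target features (Lean_max, APA size), the identifier
minimizes the two normalized residuals simultaneously (sum of squares
for optimization; the combined L1 value is reported as the objective).
The search is bounded ($K_P \in [5, 300]$ N m/deg,
$K_{FF} \in [0, 30]$, enclosing the published range of both groups with
margin) and multi-started: a deterministic 5×5 grid screen, plus one
seeded start per stable grid row found by bisecting $K_{FF}$ to match the
target APA size — exploiting the monotone growth of APA size in
$K_{FF}$, which places a start inside the narrow valley a coarse grid
straddles. The best starts are refined with bounded quasi-Newton
(finite-difference steps large enough to see past sample-quantization
kinks) and a derivative-free polish. Optima that match the features to
below 1e-6 combined residual are treated as ties and broken toward the
smallest $K_P$, then $K_{FF}$: at high $K_P$ Lean_max saturates and the
feature map loses injectivity, and the tie-break makes the returned
solution well-defined there. A damped-Newton exact two-equation root
finder is available (`method = "root"`) for targets interior to the
feature surface.

## Synthetic cohorts

The generator emulates the *statistical structure* of a two-group LoS
study: per-direction group means of the temporal parameters and gains are
the published normative values (see `group_parameter_defaults()`), and
demographics use the published group means/SDs. Quantities the study does
not publish are explicit assumptions, configurable and labelled as such:

- between-subject spread: 15 % coefficient of variation around each
  group-direction mean, truncated to physiologic bounds (rejection
  sampling, clamped after 1000 attempts);
- gain–clinical correlations: a latent severity factor shared between the
  clinical scores (UPDRS up, functional reach down; loading 0.8) and the
  gains of configured directions (loading 0.75), giving |ρ| ≈ 0.6 where
  strong correlations are reported ($K_P$–UPDRS backward, $K_P$–FRT
  forward and negative, $K_{FF}$ in directions 1, 5, 7) and ≈ 0
  elsewhere.

What the generator does **not** emulate: postural sway and its spectral
structure, within-session fatigue or learning across the four
repetitions, medication state, two-segment (hip) strategies, sensory
delays, and any nonlinearity of real COP geometry. Passing tests
therefore demonstrate the pipeline's internal consistency on trials the
model itself can produce, not agreement with raw patient recordings.

A cohort of 24 + 24 subjects with these defaults reproduces the
qualitative study pattern — $K_P$ larger in the patient group and
$K_{FF}$ larger in controls, at $p < 0.01$ in all eight directions — in
essentially every seeded replicate, which the acceptance suite checks
across 50 seeds.

## Statistics

Per direction and parameter the groups are compared with an independent
two-sample t-test; Welch's variant is the default (unequal group
variances are plausible), Student's pooled test is available for strict
replication. No multiple-testing correction is applied by default,
mirroring the protocol's standard analysis; Holm adjustment is a flag.
Gain–clinical association uses Spearman's rank correlation with
average-rank ties, within the scored (patient) group.

## Design decisions and known limitations

- **Feedback-induced APA floor.** Under the ZMP output equation *any*
  acceleration toward the target displaces the COP away from it, so even
  a pure-feedback reach ($K_{FF} = 0$) shows a small APA-like excursion
  (of order 0.1–0.5 cm at physiologic gains). APA size is therefore
  monotone in $K_{FF}$ but does not vanish at zero feedforward; a model
  in which APA size → 0 exactly would need a COP output without the
  acceleration term, which would then produce no APA at all.
- **Blend discontinuity.** The printed mixing rule jumps from pure
  feedforward back to feedback at the end of the APA window. The COP
  (which contains $\ddot\theta$) jumps with it, so the APA extremum is a
  cusp; the 80 Hz sample nearest the cusp sits up to ~2 % short of the
  full-rate extremum, and at large $K_{FF}$ the post-APA rebound can
  exceed the reach peak. Identification remains well-posed because the
  forward map is deterministic, but the peak-based reaching time is then
  a biased estimator of the planned $t_f$ — so batch identification from
  re-estimated plans is reliable in the moderate-gain regime and biased
  in the violent one. Round-trip recovery with the plan held fixed is
  accurate to ≪ 1 % (median) across the physiologic gain range.
- **Non-identifiability at extreme gains.** Outside the physiologic
  range (very high $K_P$ with small $K_{FF}$) distinct gain pairs can
  produce numerically identical feature pairs; the tie-break makes the
  answer deterministic but cannot recover information the features do
  not carry.
- The intrinsic ankle parameters, the COM-height coefficient and the
  inertia formula are conventions, not measurements; all are exposed in
  the constructors.
- Problem sizes in the test and acceptance suites (10–20 planted pairs,
  10×10 feature surfaces, 24 + 24 subjects, 20–50 seed replicates) were
  chosen as the smallest sizes at which the checked statistics are
  stable.
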