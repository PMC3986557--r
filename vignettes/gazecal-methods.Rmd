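---
title: "Mobile gaze calibration: models, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mobile gaze calibration: models, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecal)
```

This vignette documents the science implemented in **gazecal**: the two
point-of-regard (POR) estimators, the synthetic-session generator used to
test them, and the numerical and design choices that were genuinely open.
It states no empirical result that the package's test suite does not
itself compute.

## 1. Problem and coordinate conventions

A mobile participant looks at a large planar display while a motion
tracker reports the 6-DOF head pose **h** (position in cm plus three Euler
angles) and a head-mounted camera reports the pupil centroid **p** in
image units. The task is to map (**h**, **p**) to the on-screen POR in
pixels, after a calibration session in which the participant fixates known
targets.

*World frame.* Right-handed, origin at the screen center: x is the rest
gaze direction (pointing from the viewer toward the screen), y the
viewer's left, z up. The screen is the plane x = 0 and a screen-facing
head has all Euler angles equal to zero. This frame was chosen over the
superficially natural "x right / y up / z toward viewer" alternative
because, combined with a Z–Y–X Euler convention, that alternative places
every screen-facing head at exactly ±90° pitch — the gimbal-lock
singularity — so angle round-trips would be ill-conditioned precisely at
the typical operating pose. Any consistent convention is admissible (the
underlying hardware convention is not part of the method); all package
tests are convention-internal.

*Euler convention.* Intrinsic Z–Y–X: yaw ψ about the up axis, pitch θ
about the lateral axis, roll φ about the forward axis,
R = R_z(ψ) R_y(θ) R_x(φ). Gimbal lock (θ = ±90°, looking straight up or
down) is handled by a documented canonical branch (ψ = 0), never an error.
Public interfaces use degrees; internals use radians.

*Pixel convention.* Origin top-left, u rightward, v downward; the center
pixel maps to the screen center point. The screen model carries an
explicit in-plane "up" vector (the world up axis projected into the
plane), which completes the printed parameter set (center, normal, metric
size, resolution) into a well-defined 2-D frame; for a vertical planar
display this is the unique natural completion.

## 2. The geometric estimator

Three chained models:

1. **Head-to-eye transform** δ_T = (x, y, z, φ_T, θ_T, ψ_T): the eye
   position is the tracked head position plus the head-rotated offset,
   e = h + R_h (x, y, z)ᵀ, and the eye orientation is R_e = R_h R_T.
2. **Linear eye model** δ_E: φ = m_φ p_x + b_φ, θ = m_θ p_y + b_θ. The
   linearity is an efficiency-motivated approximation that holds well when
   the camera faces the eye; a spherical-projection alternative is a known
   refinement and deliberately out of scope here.
3. **Screen model** δ_S: the gaze ray g = R_e R_z(φ) R_y(θ) (1, 0, 0)ᵀ is
   intersected with the display plane, and the intersection point is
   converted to pixels. The inverse mapping (known POR and eye pose →
   required eye rotations) is what makes calibration tractable.

**Calibration.** Given session data {(h_i, p_i), (u_i, v_i)}, the cost is
the mean Euclidean pixel distance between predicted and true PORs; rays
that miss the screen plane contribute a fixed penalty of twice the screen
diagonal (mean rather than sum, so costs compare across dataset sizes).
The source method optimizes all free parameters "simultaneously" without
prescribing a schedule; here the outer bounded search runs over the six
δ_T parameters only, and for each candidate δ_T the four δ_E parameters
are fitted exactly in closed form by regressing the geometrically required
eye rotations (inverse screen model applied to the known targets) onto the
pupil coordinates. Because the eye model is linear, this realizes the
inner minimization without a second nonlinear search and removes four
dimensions from the search space exactly.

*Optimizer.* The reference implementation used BOBYQA; no bounded
derivative-free quadratic-model optimizer is available in this
environment, so the outer search uses box-constrained quasi-Newton
(`optim(method = "L-BFGS-B")`, finite-difference gradients; box ±30 cm,
±45°) from a small deterministic multistart. The recovery test suite — not
the optimizer brand — is the acceptance criterion, and it passes: on
noiseless simulated sessions the calibrated model reproduces held-out PORs
to well under 0.1° mean combined error. (δ_T, δ_E) are jointly
non-identifiable up to a gauge (e.g. a yaw offset in R_T trades exactly
against b_φ), so recovery is asserted on predictions, never on raw
parameters.

**Screen calibration.** The display geometry is user-independent and can
be estimated once from a corpus of sessions: a bounded search over the
screen center (3), normal direction (2 spherical angles; in-plane roll is
fixed by world-up), and optionally metric size (2), minimizing the sum
over users of the per-user minimized cost — each objective evaluation
re-runs the user calibration on a uniformly subsampled subset (default
500 samples per user). Pixel resolution comes from the shape prior and is
never searched. Both fixed-size and free-size modes are exposed, since
labs often know the physical display dimensions. The aggregation across
users is a plain sum (the source method does not print it); the outer
optimizer is `nlminb` (PORT) because R's L-BFGS-B is not reentrant and the
objective itself runs bounded inner searches. The returned screen is never
worse than the initial one (best-so-far contract).

## 3. The regression estimator

Per screen axis, a zero-mean Gaussian process over the 8-D input
x = (h_x, h_y, h_z, h_φ, h_θ, h_ψ, p_x, p_y):

* Kernel: K_ij = k(x_i, x_j) + σ_n² δ_ij with the ARD kernel
  k(x_i, x_j) = σ_s exp(−½ Σ_d |x_id − x_jd| / l_d) — exponential decay in
  the length-scale-weighted **absolute** per-dimension distance, exactly
  as printed in the source method. That printed form may be a typesetting
  loss of a squared term; since this cannot be resolved from the text, the
  squared-exponential variant is available behind `kernel = "sq"` and the
  as-printed form is the default. Model files record the flag.
* Prediction: μ* = K* K⁻¹ y and Σ* = K** − K* K⁻¹ K*ᵀ, via one Cholesky
  factorization with K⁻¹y precomputed; predictive standard deviations are
  the POR confidence scores.
* Hyperparameters Θ = (σ_s, σ_n, l_1 … l_8) maximize the log marginal
  likelihood −½ yᵀK⁻¹y − ½ log|K| − (n/2) log 2π, optimized in log space
  with analytic gradients and box bounds [log 10⁻⁶, 10] (the upper bound
  realizing the printed (0, e^10] range), starting from all parameters
  equal to 1 as specified.

*A necessary extra start.* With raw tracker units (pixel targets with
means of several hundred; pupil coordinates spanning thousands of units),
the all-ones start lies in a flat "everything is noise" basin: every
off-diagonal kernel entry underflows, the likelihood gradient with respect
to the length scales vanishes, and gradient ascent converges to a model
that explains the data as pure noise. One additional data-scaled start
(length scales at the per-dimension spread, signal variance near the
target variance, clamped into the box) is therefore tried and the better
optimum kept. The specified post-condition — the achieved likelihood is
never below the all-ones start's — is preserved, and the all-ones start
remains first.

*Numerics.* Factorizations use adaptive diagonal jitter (10⁻¹⁰ up to
10⁻⁴, then error). Predictive variances are clipped at zero, with a
warning below −10⁻⁸. Hyperparameters are fitted on a uniformly subsampled
subset (default 500 rows); kernel matrices are then built on the full
calibration set, capped at 2000 rows to bound the O(n³) factorization.
Inputs are not standardized — the ARD length scales absorb scale, matching
the source method's silence on the point.

## 4. The session simulator

The simulator is the package's stated world, not a tuning knob: its
defaults are the protocol constants of the experimental design it
emulates, and the remaining choices were fixed once at values a
practitioner would call realistic.

* **Stimuli.** Dynamic phase: a dot moving horizontally or vertically at
  100 px/s for at least 100 px per segment (segment lengths uniform in
  [100, 300] px, clipped at a 20 px screen margin), pausing 750 ms at each
  random change to one of the three alternative cardinal directions;
  duration 180 s. Where the protocol does not state the starting point or
  first direction, both are uniform-random. Static phase: ten random
  permutations of a 5×4 grid spanning ±32° × ±23° of visual angle from the
  140 cm chin-rest position — 200 presentations of 1500 ms, 300 s total.
* **Head motion.** No motion model is part of the source method (real
  humans supplied it), so this is simulator-internal: head-fixed is a
  constant chin-rest pose plus sensor noise; head-free keeps the position
  fixed and lets orientation face the current stimulus with stationary
  Ornstein–Uhlenbeck deviations (sd 6°, time constant 1.5 s); walking adds
  an OU positional walk (sd 35 cm, time constant 8 s) reflected into the
  150 × 145 cm floor area in front of the display.
* **Forward model.** Fixation is modeled as exact (the calibration
  premise): the required eye rotations follow from the inverse screen
  model and the pupil sample from the inverted linear eye model, plus
  Gaussian sensor noise (defaults: pupil 2.5 image units ≈ 0.05°, head
  position 0.05 cm, head orientation 0.1° — typical video/IR tracker
  precision; an optional fixation-jitter term exists for robustness
  experiments). Ground truth defaults: eye 8 cm forward and 9 cm below
  the tracked markers, zero rotation offset; eye-model slope 0.02 °/unit.
* **Rates.** One unified sample rate (default 60 Hz) replaces the mixed
  250/60 Hz hardware rates; mixed-rate real recordings are handled at
  load time by `align_streams()` (linear interpolation for positions and
  pupil, shortest-arc quaternion slerp for orientations — an assumption
  of this artifact, since the original synchronization is not described).

What a green simulation-based test establishes: that each estimator
recovers the generating mapping under its own modeling assumptions, at
the stated noise levels, and that the coverage mechanism (below) behaves
as described. What it does not establish: robustness to eye-model
non-linearity, helmet slippage and drift, blinks, or imperfect fixation —
phenomena real sessions contain and the simulator deliberately omits.

## 5. Evaluation protocol

Sessions are split per phase at 2 minutes: Calib-Dynamic / Valid-Dynamic,
and — after reducing the static phase to stable fixations by discarding
the first 1250 ms of every presentation and keeping the final 250 ms —
Calib-Static / Valid-Static. Training never uses Calib-Static alone.
Errors are expressed in degrees of visual angle from the current head
position: the combined error is the angle between the head→estimated-POR
and head→true-POR vectors (frame-independent, the primary metric);
azimuth/elevation are differences of world-frame spherical coordinates,
one admissible reading of a decomposition the protocol leaves undefined.

The coverage-overlap statistic bins the 5-D (h_x, h_y, h_z, p_x, p_y)
space at 10 cm / 1500 image units (half-open bins anchored at the origin;
the pupil bin width is a parameter since units differ across trackers)
and reports |bins occupied by both| / |bins occupied by validation|. Of
the two readings of the denominator phrase the all-validation-bins one is
the default (it yields a proportion in [0, 1]); the exclusive reading is
available behind a flag. The regression method's predictive sigma enables
principled rejection of unreliable PORs (default threshold 75 px mean
sigma, the saturation level of the reliability scale).

## 6. Known limitations

* The linear eye model ignores projection non-linearity at large
  eccentricities; the geometric method inherits this bias.
* The GP is O(n³) in training rows; the 2000-row cap trades accuracy for
  tractability on long sessions. Sparse approximations are out of scope.
* Raw-parameter identifiability of δ_T/δ_E is gauge-limited by design;
  consumers should treat the prediction function, not the coefficients,
  as the calibrated object.
* The simulator's OU motion model is statistically, not biomechanically,
  realistic (no gait cycle, no vestibulo-ocular dynamics, no saccade
  kinematics).
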