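---
title: "Actuator compliance and virtual ligament forces in joint-simulator testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actuator compliance and virtual ligament forces in joint-simulator testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligsim)
```

## The problem this package models

Six degree-of-freedom joint simulators test total knee replacements (TKR) by
articulating the femoral and tibial implant components against each other
under controlled loads. To stand in for the resected soft tissues, such
machines offer a *virtual ligament model*: software force elements spanning
between insertion points fixed to each component, whose resultant the machine
applies through its actuators. The insertion-point positions are computed
from the actuators' joint-coordinate sensors.

That computation silently assumes a rigid machine. In reality the upper
actuator's gimbal arms deflect elastically under the high compressive loads
typical of the knee (of order 1 mm per kN). The deflection is not captured by
the angle sensors, so the machine computes ligament lengths from a pose that
differs from the true one by the unsensed deflection: virtual ligaments
appear shortened whenever the contact force is high, and their computed
forces drop accordingly. `ligsim` models this artifact quantitatively, and
evaluates the standard mitigation: *preloading* the components while the
reference configuration is set, so that the error vanishes at the preload
and is small near it.

The package contains two parallel simulation paths built from the same
mechanical ingredients:

* a **ground-truth model** (`run_reference_flexion()`): rigid quasi-static
  equilibrium between implant contact and ligament forces, the analogue of a
  multibody simulation of the same joint;
* an **emulator** (`run_passive_flexion()`): the same equilibrium, except
  that the applied ligament wrench is computed at the compliance-corrupted
  *sensed* pose while contact acts at the true pose.

With the compliance curve disabled the two coincide, which is the package's
primary self-check.

## Ligament force law

Each bundle is a tension-only fiber between an origin fixed in the femoral
component frame and an insertion fixed in the tibial component frame, with
engineering strain $\epsilon = (L - L_0)/L_0$. The force law is the standard
quadratic-to-linear form used throughout the knee-ligament literature:

$$
f(\epsilon) \;=\;
\begin{cases}
0 & \epsilon \le 0\\[2pt]
k\,\epsilon^2 / (4\epsilon_\ell) & 0 < \epsilon \le 2\epsilon_\ell\\[2pt]
k\,(\epsilon - \epsilon_\ell) & \epsilon > 2\epsilon_\ell
\end{cases}
$$

with stiffness $k$ in N per unit strain and the quadratic-to-linear
transition at $2\epsilon_\ell = 6\,\%$ strain by default. The form is
$C^1$-continuous; both one-sided slopes at the transition equal $k$. The
rest length $L_0$ is never entered directly: it is *calibrated* from the
insertion-point distance at the reference configuration and the reference
strain $\epsilon_r$ assigned there, $L_0 = L_{\mathrm{ref}}/(1+\epsilon_r)$.
Virtual resection scales a bundle's force by `stiffness_scale` in $[0,1]$
without touching its calibration, so force at scale $s$ is exactly $s$ times
the force at scale 1.

The exemplary bench fiber (`make_exemplary_lcl_fixture()`) uses $k = 3300$ N
per unit strain, $\epsilon_r = 0.11$ and a vertical line of action. Its rest
length of 46.5 mm is a fixture constant: it is the unique value (to the
printed precision) at which shortening the fiber by the maximal unsensed
deflection of 2.2 mm brings the computed force to the reported endpoint near
108 N; the test suite re-derives it by a brute-force one-dimensional search.

## Actuator compliance model

Measured load-deflection curves of the upper actuator rise degressively up
to a break load and almost linearly beyond it. We model the vertical
deflection $s(F)$ as a power law below the break load $F_b$ and a straight
line above it,

$$
s(F) = s_b\,(F/F_b)^p \;\; (F \le F_b), \qquad
s(F) = s_b + m\,(F - F_b) \;\; (F > F_b),
$$

with the exponent fixed by $C^1$ continuity at the break, $p = m F_b / s_b$.
Only three anchors are therefore calibrated, all measured at 0° flexion-arm
rotation where compliance is maximal: $F_b = 500$ N, $s_b = 0.7$ mm and
$m = 0.6$ mm per 1000 N. This gives $p = 3/7$ and, e.g., $s(3000\,\mathrm{N})
= 2.2$ mm. The power-law shape below the break load is a modeling choice:
only the qualitative degressive shape of the measured curve is known there,
and $C^1$ matching removes the free parameter. Arm-angle dependence enters
as multiplicative factors per stored angle (1.0 at 0°); the non-zero-angle
defaults (0.9/0.8/0.7 at 30°/60°/90°) are configurable placeholders, are
interpolated linearly, and are not used by any quantitative result in the
package. The deflection is lumped into a single scalar acting along the
distal-proximal axis, matching how it is measured; bending and torsion of
the arm segments are folded into that scalar.

## Kinematics

`joint_pose()` holds the six coordinates (flexion, adduction, internal
rotation in degrees; anterior, medial, proximal translations in mm, right
knee). The rotation sequence is Grood-Suntay style: flexion about the
femoral gimbal axis, adduction about the floating anterior axis, internal
rotation about the tibial mechanical axis. Translations are expressed in the
tibial frame so that the distal-proximal coordinate always acts along the
mechanical tibial axis, which is the direction of the compliance deflection.
The machine's own convention is not published; results reported at 80° or
less flexion are insensitive to this choice, but cross-study comparison of
rotation magnitudes is approximate. Femoral AP displacement is reported as
the negated tibial AP coordinate, relative to the reference configuration at
0° flexion.

## Contact model

Implant contact uses an elastic foundation: penetration is sampled at the
face centroids of the tibial surface against the femoral mesh (signed
distances from angle-weighted pseudonormals, computed in compiled code), and
pressure is proportional to depth with `foundation_modulus` (default
30 N/mm³, the order of magnitude of a UHMWPE foundation stiffness).
Tangential traction is regularized Coulomb friction, with the per-sample
slip measured against the previous quasi-static step and saturation
smoothed over `regularization_slip` (default 0.3 mm per step — small
compared with the millimetre-scale per-step slip of a flexion sweep, so
sustained sliding sees the full Coulomb force, while slip reversals remain
numerically benign). The default friction coefficient is 0.04 (lubricated
metal-on-polyethylene); it is exposed because raising it visibly shifts the
femur posteriorly during flexion (rolling dominating sliding), a mechanism
check in the test suite. An elastic foundation was chosen over re-implementing
a polygonal contact algorithm because it reproduces the quasi-static
normal/tangential behavior needed here and is the standard approach for TKR
contact mechanics. Quadrature ties (coincident closest features) resolve to
the smallest face index, so the model is deterministic.

## Equilibrium solving

Flexion is position-controlled; the remaining five coordinates are
force-controlled (whether adduction is force- or position-controlled on the
physical machine during passive flexion is not documented; five free DOFs is
the default and is switchable). At each flexion angle the solver drives the
generalized forces of the contact wrench (true pose) plus applied ligament
wrench (sensed pose) to zero: tolerance 0.5 N on forces and 50 N·mm on
moments. Generalized forces are wrenches projected onto numeric twists of
each free coordinate, which accounts exactly for the kinematic coupling of
the rotation sequence. The iteration is a damped Newton / Levenberg-Marquardt
scheme on a central-difference Jacobian (step $10^{-3}$ mm or degrees,
widened fivefold once if progress stalls, which averages over the faceting
of the contact meshes). The sensed-pose deflection is an explicit function
of the axial contact force, so it sits directly inside the residual; no
inner fixed-point iteration is needed. Sweeps warm-start each angle from the
previous solution and bisect the flexion increment (down to 0.25°) on
non-convergence; a step that still fails is flagged in the result rather
than silently accepted, and a sweep aborts with a partial result after two
consecutive flagged steps. Loss of contact is solved with a zero contact
wrench and a warning.

The reference configuration is self-consistent: bundle rest lengths are
defined at the 0°-flexion equilibrium, which itself depends on the
calibration, so `find_reference_pose()` iterates calibration and equilibrium
to a fixed point (pose change below $10^{-3}$ mm/deg).

## Synthetic fixture

No implant geometry or cadaver ligament data are redistributable, so the
fixture is synthetic by design (`fixture_spec()`,
`make_implant_surfaces()`, `make_ligament_set()`):

* **Surfaces** — two toroidal femoral condyle patches (sagittal outer radius
  35 mm, frontal radius 20 mm, centers 44 mm apart) on two paraboloid tibial
  dishes (sagittal/frontal radii 45/24 mm), meeting exactly at the zero
  pose. A single sagittal radius (no decreasing-radius "J-curve") is the
  simplest geometry that still yields rising ligament tension, femoral
  rollback and rotation coupling.
* **Ligaments** — 16 bundles: 2 PCL, 3 MCL, 3 LCL, 1 opMCL, 2 dMCL, 2 OPL,
  1 APL, and one medial and lateral posterior capsule bundle. Coordinates
  and stiffnesses are fixture constants standing in for unpublished
  cadaver-derived sets: collaterals sit at the epicondyles close to the
  flexion axis and slacken gradually; the posterior capsule is pretensioned
  in extension and releases within the first 10-15° of flexion; the PCL is
  placed so that its length grows monotonically with flexion, becoming taut
  near 45-50° — the geometric requirement behind the late-flexion resection
  effects. An optional seeded jitter (default 0 mm) supports robustness
  studies; the `"symmetric"` variant mirrors the medial structures for
  symmetry checks.

On this fixture the 0°-flexion equilibrium carries an axial force around
1 kN which decays with flexion as the posterior structures release, with the
PCL re-tensioning the joint late in flexion. What passing tests show is that
the *mechanisms* — force-level depression under low preload, error-sign
reversal around the preload, convergence of preload variants with flexion,
resection effects confined to late flexion — emerge from the model; the
magnitudes are properties of the synthetic fixture, not predictions for any
commercial implant. Features of real tests that the fixture deliberately
omits: patellar articulation, ligament wrapping (not representable in
virtual ligament models), viscoelasticity, lubricant rheology, servo control
dynamics (the machine's iterative learning control is replaced by exact
quasi-static equilibrium, mirroring the evaluation of converged cycles), and
sensor noise.

## Problem sizes and runtime choices

The package defaults aim at routine desk use: mesh resolution 16 (about 800
femoral and 1300 tibial faces — enough that flat-on-flat quadrature is
accurate to 1 % and the equilibrium path is smooth), flexion schedules of
0-80° in steps of at most 2° (the protocol validates the 2° bound), and the
experiment drivers default to 2° steps. Tests and the acceptance analyses
use these sizes; finer meshes and 1° or 0.5° schedules change runtimes, not
conclusions.

## Known limitations

* The piecewise-linear mesh makes the contact gradient only piecewise
  smooth; isolated steps may be flagged at force residuals of 1-2 N
  (0.1-0.3 % of the load level) instead of the 0.5 N tolerance.
* The compliance scalar ignores load direction: shear and moment loading of
  the gimbal arms are not separately modeled.
* Only the 0° arm-rotation compliance curve is quantitative.
* The fixture's ligament recruitment sequence is plausible but synthetic;
  absolute force levels and rollback magnitudes should not be compared
  numerically against measurements of any physical TKR.
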