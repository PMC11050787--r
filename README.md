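# ligsim — virtual-ligament joint-simulator emulation for TKR testing

Six degree-of-freedom joint simulators test total knee replacements (TKR)
with a *virtual ligament model*: software force elements between insertion
points fixed to the femoral and tibial implant components, whose resultant
the machine applies through its actuators. Because insertion-point positions
are computed from the actuator joint sensors, any unsensed elastic
deflection of the actuator structure corrupts the computed ligament lengths
— under kN-scale knee loads the upper actuator deflects by millimetres, the
virtual ligaments appear shortened, and their computed forces drop.

`ligsim` is an R package for biomechanics and implant-testing researchers
that models this artifact end to end and evaluates the standard mitigation
(preloading the components while the reference configuration is set). It
provides:

* the quadratic-to-linear (Wismans/Blankevoort) ligament force law
  f(ε) = k ε²/(4 ε_ℓ) for 0 < ε ≤ 2 ε_ℓ and k (ε − ε_ℓ) beyond, tension
  only, with rest lengths calibrated from a reference strain ε_r at the
  reference configuration;
* a calibrated degressive-then-linear actuator compliance curve
  s(F) = s_b (F/F_b)^p below the break load and s_b + m (F − F_b) above,
  with p = m F_b / s_b fixed by C¹ continuity (defaults: 0.7 mm at 500 N,
  0.6 mm per 1000 N);
* Grood–Suntay style six-coordinate tibiofemoral kinematics;
* elastic-foundation implant contact with regularized Coulomb friction on
  triangle meshes (compiled signed-distance kernel);
* a rigid ground-truth quasi-static knee model and a simulator *emulator*
  in which contact acts at the true pose while the applied ligament wrench
  is computed at the compliance-corrupted sensed pose;
* synthetic fixtures (bicondylar implant meshes, a 16-bundle ligament
  apparatus, bench compliance anchors) so everything runs without any
  external data;
* experiment drivers for the passive-flexion comparison, the preload study
  and virtual PCL-resection sweeps.

## Worked example: sensed ligament force under a vertical load ramp

A single pretensioned vertical virtual ligament (stiffness 3300 N per unit
strain, 11 % reference strain, rest length 46.5 mm) is held between the
actuators while the vertical contact force is ramped up. Nothing physically
moves apart — but the unsensed deflection s₁(F) shortens the *computed*
fiber, and the machine's ligament force falls:

```r
library(ligsim)
bundle <- make_exemplary_lcl_fixture()
curve  <- do.call(compliance_curve, default_compliance_anchors())
worked_example_force_vs_load(bundle, curve, c(30, 500, 1000, 2000, 3000))
```

```
 load_N  s1_mm  strain force_N
     30 0.2096 0.10549   249.1
    500 0.7000 0.09495   214.3
   1000 1.0000 0.08849   193.0
   2000 1.6000 0.07559   150.5
   3000 2.2000 0.06269   107.9
```

At the reference configuration the fiber carries
`force_from_strain(0.11, 3300, 0.03)` = 264 N; at 3000 N vertical load the
unsensed 2.2 mm deflection has cut the sensed force to 107.9 N, a −59 %
change — with a perfectly rigid actuator the column would be constant.
Full flexion experiments run the same way:

```r
cfg <- experiment_config("flexion_compare", out_dir = "out")
run_experiment(cfg)   # ground-truth model + emulator at 800 N and 100 N preload
```

which writes per-run CSVs (axial force, tibial rotation, femoral AP
displacement, per-bundle sensed/true ligament forces per flexion angle) and
a JSON summary. On the default synthetic fixture the run preloaded with
100 N shows a clearly depressed axial-force level relative to the 800 N
run, the two converge with increasing flexion, and sensed ligament forces
under-read exactly where the contact force exceeds the preload.

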