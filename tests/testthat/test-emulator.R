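# Simulator emulation: reference configuration, sensed poses, worked example
# and single-step equilibrium.

test_that("reference deflection follows the compliance curve branch values", {
  curve <- fx_curve()
  app <- make_ligament_set()
  pose <- joint_pose(dp = 0.3)
  rc800 <- set_reference_configuration(pose, 800, curve, app)
  expect_equal(rc800$reference_deflection, 0.7 + 6e-4 * 300)
  rc0 <- set_reference_configuration(pose, 0, curve, app)
  expect_equal(rc0$reference_deflection, 0)
  rc100 <- set_reference_configuration(pose, 100, curve, app)
  expect_equal(rc100$reference_deflection, 0.7 * (100 / 500)^(3 / 7))
  expect_equal(rc100$reference_deflection, 0.35, tolerance = 0.01)
  # calibration happened at the reference pose
  tr <- pose_to_transform(pose)
  for (b in rc800$apparatus$bundles)
    expect_equal(ligsim:::.bundle_strain(b, tr), b$reference_strain,
                 tolerance = 1e-9)
  expect_error(set_reference_configuration(pose, -5, curve, app))
})

test_that("sensed pose shifts only distal-proximal and vanishes at preload", {
  curve <- fx_curve()
  p <- joint_pose(flexion = 20, ap = 1, dp = 0.5)
  delta_ref <- displacement_at_load(curve, 800)
  # at the preload the sensed pose equals the true pose
  s <- sensed_pose_from_true(p, 800, curve, delta_ref)
  expect_equal(unlist(s), unlist(p))
  # high load with no preload compensation: 2.2 mm apparent approach
  s2 <- sensed_pose_from_true(p, 3000, curve, 0)
  expect_equal(s2$dp - p$dp, 2.2)
  for (nm in c("flexion", "adduction", "internal", "ap", "ml"))
    expect_equal(s2[[nm]], p[[nm]])
  # below the preload the shift reverses sign
  s3 <- sensed_pose_from_true(p, 100, curve, delta_ref)
  expect_lt(s3$dp, p$dp)
  # rigid simulator: sensed is true at any load
  expect_equal(unlist(sensed_pose_from_true(p, 3000, NULL, 0)), unlist(p))
})

test_that("worked example: sensed force falls with load, constant if rigid", {
  b <- make_exemplary_lcl_fixture()
  curve <- fx_curve()
  tab <- worked_example_force_vs_load(b, curve, seq(0, 3000, by = 50))
  expect_true(all(diff(tab$force_N) < 0))
  expect_equal(tab$force_N[1], 264)
  expect_equal(tab$s1_mm[tab$load_N == 3000], 2.2)
  rigid <- worked_example_force_vs_load(b, NULL, c(0, 1000, 3000))
  expect_true(all(rigid$force_N == rigid$force_N[1]))
})

test_that("flexion protocol validates its schedule", {
  expect_error(flexion_protocol(c(0, 5, 3)), "increasing")
  expect_error(flexion_protocol(c(0, 3)), "<= 2")
  expect_error(flexion_protocol(seq(0, 10, 1), free_dofs = "flexion"))
  p <- flexion_protocol(seq(0, 10, 0.5), preload = 100)
  expect_identical(length(p$schedule), 21L)
})

test_that("symmetric fixture stays in the sagittal plane at full extension", {
  surf <- fx_surfaces()
  law <- fx_law()
  app <- make_ligament_set("symmetric")
  ref <- find_reference_pose(app, surf, law)
  # force residuals settle to within a couple of N of the load level
  r <- ref$solution$residual
  expect_lt(max(abs(r[3:5])), 2)
  expect_lt(abs(ref$pose$ml), 0.05)
  expect_lt(abs(ref$pose$adduction), 0.05)
})

test_that("solver reports loss of contact when surfaces are separated", {
  surf <- fx_surfaces()
  law <- fx_law()
  # one long slack bundle, tibia hanging well below the femoral component
  b <- ligament_bundle("drop", c(0, 0, 0), c(0, 0, -60), 100, -0.5)
  app <- calibrate_apparatus(ligament_apparatus(list(b)),
                             pose_to_transform(joint_pose(dp = -5)))
  expect_warning(
    sol <- solve_step_equilibrium(0, joint_pose(dp = -5), app, surf, law),
    "loss of contact")
  expect_true(sol$lost_contact)
  expect_equal(sol$contact$force, c(0, 0, 0))
})

test_that("with a near-rigid compliance curve the emulator reproduces the
           ground-truth equilibrium at single steps", {
  surf <- fx_surfaces(); law <- fx_law()
  ref <- fx_reference()
  rc <- set_reference_configuration(ref$pose, 0, fx_rigid_curve(),
                                    fx_apparatus())
  for (ang in c(0, 30)) {
    prev <- ligsim:::.pose_set(ref$pose, "flexion", ang)
    st_em <- solve_step_equilibrium(ang, prev, rc$apparatus, surf, law,
                                    fx_rigid_curve(), rc)
    st_gt <- solve_reference_equilibrium(ang, prev, rc$apparatus, surf, law)
    for (nm in c("ap", "ml", "dp"))
      expect_equal(st_em$pose[[nm]], st_gt$pose[[nm]], tolerance = 0.01)
    for (nm in c("adduction", "internal"))
      expect_equal(st_em$pose[[nm]], st_gt$pose[[nm]], tolerance = 0.01)
  }
})

test_that("flexion results serialize with per-bundle force columns", {
  run <- fx_reference_run()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_flexion_csv(run, path)
  df <- read.csv(path)
  expect_identical(nrow(df), nrow(run$steps))
  expect_true(all(c("sensed_PCL_al", "true_PCL_al") %in% names(df)))
  expect_equal(df$axial_force_N, run$steps$axial_force_N)
})
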