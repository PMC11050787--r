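# Quadratic-to-linear force law and ligament apparatus mechanics.

test_that("force law reproduces the closed-form branch values", {
  # slack
  expect_identical(force_from_strain(0, 3300, 0.03), 0)
  expect_identical(force_from_strain(-0.5, 3300, 0.03), 0)
  # junction at 2 * eps_l: both branches give k * eps_l
  expect_equal(force_from_strain(0.06, 3300, 0.03), 3300 * 0.03)
  expect_equal(3300 * 0.06^2 / (4 * 0.03), 3300 * (0.06 - 0.03))
  # linear branch at the exemplary reference strain
  expect_equal(force_from_strain(0.11, 3300, 0.03), 264)
  # strain after 2.2 mm shortening of the 46.5 mm fixture bundle
  strain <- (46.5 * 1.11 - 2.2) / 46.5 - 1
  expect_equal(force_from_strain(strain, 3300, 0.03), 107.87, tolerance = 1e-4)
})

test_that("force law is continuous, C1 at the transition, and monotone", {
  for (k in c(500, 3300, 9000)) {
    for (eps_l in c(0.01, 0.03, 0.08)) {
      h <- 1e-8
      f_lo <- force_from_strain(2 * eps_l - h, k, eps_l)
      f_hi <- force_from_strain(2 * eps_l + h, k, eps_l)
      expect_lt(abs(f_hi - f_lo), 3 * k * h)
      # one-sided slopes both equal k at the junction
      s_lo <- (force_from_strain(2 * eps_l, k, eps_l) - f_lo) / h
      s_hi <- (f_hi - force_from_strain(2 * eps_l, k, eps_l)) / h
      expect_equal(s_lo, k, tolerance = 1e-5)
      expect_equal(s_hi, k, tolerance = 1e-5)
      eps <- seq(-0.05, 0.3, length.out = 200)
      expect_true(all(diff(force_from_strain(eps, k, eps_l)) >= 0))
    }
  }
})

test_that("rest length derives from the reference distance and round-trips", {
  expect_equal(rest_length_from_reference(c(0, 0, 0), c(0, 0, -51.615), 0.11),
               46.5)
  expect_equal(rest_length_from_reference(c(0, 0, 0), c(10, 0, 0), 0), 10)
  expect_error(rest_length_from_reference(c(1, 2, 3), c(1, 2, 3), 0.1),
               "degenerate")
  set.seed(42)
  for (i in 1:20) {
    p <- rnorm(3, sd = 30); q <- rnorm(3, sd = 30)
    if (sum((p - q)^2) < 1e-6) next
    eps_r <- runif(1, -0.5, 0.5)
    L0 <- rest_length_from_reference(p, q, eps_r)
    expect_equal(sqrt(sum((p - q)^2)) / L0 - 1, eps_r, tolerance = 1e-9)
  }
})

test_that("bundle force is tension-only, directed insertion-to-origin", {
  b <- ligament_bundle("b", c(0, 0, 0), c(0, 0, -46.5 * 1.11),
                       stiffness_k = 3300, reference_strain = 0.11,
                       rest_length = 46.5)
  id <- pose_to_transform(joint_pose())
  bf <- bundle_force_vector(b, id)
  expect_equal(bf$magnitude, 264)
  expect_equal(bf$force, c(0, 0, 264))  # pulls the tibial point proximally
  # slack: move tibia up so the fiber is shorter than rest length
  slack <- pose_to_transform(joint_pose(dp = 10))
  expect_equal(bundle_force_vector(b, slack)$force, c(0, 0, 0))
  # resected bundle produces nothing at any strain
  b0 <- b; b0$stiffness_scale <- 0
  expect_equal(bundle_force_vector(b0, pose_to_transform(joint_pose(dp = -5)))$force,
               c(0, 0, 0))
  # uncalibrated bundle errors
  bu <- ligament_bundle("u", c(0, 0, 0), c(0, 0, -50), 1000, 0.05)
  expect_error(bundle_force_vector(bu, id), "uncalibrated")
})

test_that("apparatus wrench is additive and mirror-symmetric pairs cancel ML", {
  id <- pose_to_transform(joint_pose())
  expect_equal(apparatus_wrench(ligament_apparatus(list()), id)$force,
               c(0, 0, 0))
  b1 <- ligament_bundle("m", c(0, 20, 0), c(0, 25, -50), 2000, 0.05)
  b2 <- ligament_bundle("l", c(0, -20, 0), c(0, -25, -50), 2000, 0.05)
  app <- calibrate_apparatus(ligament_apparatus(list(b1, b2)), id)
  w <- apparatus_wrench(app, id)
  w1 <- apparatus_wrench(ligament_apparatus(app$bundles["m"]), id)
  w2 <- apparatus_wrench(ligament_apparatus(app$bundles["l"]), id)
  expect_equal(w$force, w1$force + w2$force)
  expect_equal(w$moment, w1$moment + w2$moment)
  # sagittal mirror symmetry: no medial-lateral resultant
  expect_equal(w$force[2], 0, tolerance = 1e-12)
  # single-bundle apparatus equals that bundle's wrench
  bf <- bundle_force_vector(app$bundles$m, id)
  expect_equal(w1$force, bf$force)
})

test_that("apparatus wrench at a stretched pose pulls the tibia proximally", {
  id <- pose_to_transform(joint_pose())
  app <- calibrate_apparatus(
    ligament_apparatus(list(make_vertical_bundle("V", k = 1000, eps_r = 0.1))),
    id)
  w <- apparatus_wrench(app, id)
  expect_equal(w$force, c(0, 0, force_from_strain(0.1, 1000)))
})

test_that("resection scales matching bundles linearly and validates matches", {
  app <- fx_apparatus()
  id <- pose_to_transform(joint_pose(dp = 0.3))
  app <- calibrate_apparatus(app, pose_to_transform(joint_pose()))
  res <- set_resection(app, "PCL", 0.5)
  scaled <- vapply(res$bundles, `[[`, 0, "stiffness_scale")
  expect_identical(sum(scaled == 0.5), 2L)
  expect_true(all(scaled[!startsWith(names(scaled), "PCL")] == 1))
  expect_error(set_resection(app, "XYZ", 0.5), "no bundle matches")
  expect_error(set_resection(app, "PCL", 1.5))
  # linearity at fixed pose: force at scale s = s * force at scale 1
  tr <- pose_to_transform(joint_pose(flexion = 70))
  f1 <- apparatus_wrench(app, tr)$magnitudes
  for (s in c(0, 0.25, 0.5)) {
    fs <- apparatus_wrench(set_resection(app, "PCL", s), tr)$magnitudes
    pcl <- startsWith(names(f1), "PCL")
    expect_equal(fs[pcl], s * f1[pcl], tolerance = 1e-12)
    expect_equal(fs[!pcl], f1[!pcl])
  }
})

test_that("ligament sets survive a YAML round trip", {
  app <- fx_apparatus()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_ligament_yaml(app, path)
  app2 <- read_ligament_yaml(path)
  expect_identical(names(app2$bundles), names(app$bundles))
  for (nm in names(app$bundles)) {
    expect_equal(app2$bundles[[nm]]$origin, app$bundles[[nm]]$origin)
    expect_equal(app2$bundles[[nm]]$insertion, app$bundles[[nm]]$insertion)
    expect_equal(app2$bundles[[nm]]$stiffness_k, app$bundles[[nm]]$stiffness_k)
    expect_equal(app2$bundles[[nm]]$reference_strain,
                 app$bundles[[nm]]$reference_strain)
  }
})

test_that("bundle and apparatus constructors validate their invariants", {
  expect_error(ligament_bundle("b", c(0, 0, 0), c(0, 0, -50), -5, 0.1))
  expect_error(ligament_bundle("b", c(0, 0, 0), c(0, 0, -50), 100, 0.1,
                               stiffness_scale = 1.2))
  expect_error(ligament_bundle("b", c(0, 0, 0), c(0, 0, -50), 100, 0.1,
                               linear_limit = 0))
  b <- ligament_bundle("b", c(0, 0, 0), c(0, 0, -50), 100, 0.1)
  expect_error(ligament_apparatus(list(b, b)), "unique")
})
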