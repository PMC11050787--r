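# Synthetic fixture generators.

test_that("ligament set has the prescribed bundle counts per structure", {
  app <- make_ligament_set()
  counts <- c(PCL = 2, MCL = 3, LCL = 3, opMCL = 1, dMCL = 2, OPL = 2,
              APL = 1, mpCAP = 1, lpCAP = 1)
  nm <- names(app$bundles)
  expect_identical(length(nm), 16L)
  for (p in names(counts))
    expect_identical(sum(startsWith(nm, p)), as.integer(counts[[p]]),
                     info = p)
  # MCL count must not swallow the deep/oblique medial structures
  expect_identical(sum(startsWith(nm, "MCL")), 3L)
  expect_error(make_ligament_set("nope"))
})

test_that("fixture generation is deterministic under a fixed seed", {
  a1 <- make_ligament_set(seed = 5, jitter = 0.5)
  a2 <- make_ligament_set(seed = 5, jitter = 0.5)
  a3 <- make_ligament_set(seed = 6, jitter = 0.5)
  o1 <- t(vapply(a1$bundles, `[[`, numeric(3), "origin"))
  o2 <- t(vapply(a2$bundles, `[[`, numeric(3), "origin"))
  o3 <- t(vapply(a3$bundles, `[[`, numeric(3), "origin"))
  expect_identical(o1, o2)
  expect_false(isTRUE(all.equal(o1, o3)))
  # jitter restores the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(make_ligament_set(seed = 5, jitter = 0.5))
  expect_identical(runif(1), x1)
})

test_that("implant meshes are sagittally symmetric, oriented and sized", {
  surf <- fx_surfaces()
  expect_gte(nrow(surf$femoral$faces), 500)
  expect_gte(nrow(surf$tibial$faces), 500)
  for (s in surf) {
    v <- s$vertices
    mir <- v; mir[, 2] <- -mir[, 2]
    # reflecting about the sagittal plane maps the vertex set onto itself
    key <- function(m) sort(apply(round(m, 6), 1, paste, collapse = ","))
    expect_identical(key(mir), key(v))
    expect_true(all(face_areas(s$vertices, s$faces) > 1e-9))
  }
  expect_error(make_implant_surfaces(fixture_spec(resolution = 10)),
               "too coarse")
  expect_error(fixture_spec(dish_frontal_radius = 10), "conforming")
})

test_that("at light axial compression both condyles carry contact", {
  surf <- fx_surfaces()
  pf <- penetration_field(surf$tibial, surf$femoral,
                          pose_to_transform(joint_pose(dp = 0.1)))
  pen <- pf$points[pf$depth > 0, , drop = FALSE]
  expect_gt(sum(pen[, 2] > 0), 0)  # medial condyle
  expect_gt(sum(pen[, 2] < 0), 0)  # lateral condyle
})

test_that("exemplary bundle carries the bench-fixture constants", {
  b <- make_exemplary_lcl_fixture()
  expect_equal(b$stiffness_k, 3300)
  expect_equal(b$reference_strain, 0.11)
  expect_equal(2 * b$linear_limit, 0.06)
  expect_equal(b$rest_length, 46.5)
  expect_equal(sqrt(sum((b$origin - b$insertion)^2)), 46.5 * 1.11)
  # independent 1-D brute-force: the rest length at which a 2.2 mm
  # shortening lands on the printed 108 N is ~46.5 mm
  target <- function(L0) {
    len <- L0 * 1.11 - 2.2
    force_from_strain(len / L0 - 1, 3300, 0.03) - 108
  }
  grid <- seq(30, 70, by = 0.001)
  best <- grid[which.min(abs(vapply(grid, target, 0)))]
  expect_equal(best, 46.5, tolerance = 2e-3)
})

test_that("default compliance anchors reproduce the measured curve", {
  cc <- do.call(compliance_curve, default_compliance_anchors())
  expect_equal(displacement_at_load(cc, 500), 0.7)
  expect_equal(cc$shape_exponent, 3 / 7)
  expect_equal(1000 * cc$linear_slope, 0.6)
})

test_that("generated apparatus calibrates cleanly at the reference pose", {
  ref <- fx_reference()
  app <- ref$apparatus
  tr <- pose_to_transform(ref$pose)
  for (b in app$bundles) {
    expect_gt(b$rest_length, 0)
    expect_equal(ligsim:::.bundle_strain(b, tr), b$reference_strain,
                 tolerance = 1e-9)
  }
})

test_that("fixtures write to disk and read back", {
  dir <- tempfile("fx_")
  on.exit(unlink(dir, recursive = TRUE))
  paths <- generate_fixtures(dir, fixture_spec(resolution = 14))
  expect_true(all(file.exists(paths)))
  app <- read_ligament_yaml(paths[["ligaments_yaml"]])
  expect_identical(length(app$bundles), 16L)
})
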