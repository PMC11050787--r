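# Elastic-foundation contact: penetration field, quadrature, friction.

test_that("separated surfaces produce no penetration and zero wrench", {
  tib <- make_plate(half = 15, n = 8, z0 = 0, frame = "tibial",
                    normal = c(0, 0, 1))
  fem <- make_plate(half = 25, n = 8, z0 = 5, frame = "femoral",
                    normal = c(0, 0, -1))
  tr <- pose_to_transform(joint_pose())
  pf <- penetration_field(tib, fem, tr)
  expect_true(all(pf$depth == 0))
  w <- contact_wrench(tib, fem, tr, contact_law())
  expect_equal(w$force, c(0, 0, 0))
  expect_identical(w$n_contact, 0L)
})

test_that("flat-on-flat uniform penetration matches the closed form", {
  d <- 0.2
  law <- contact_law(foundation_modulus = 30, friction_mu = 0)
  fem <- make_plate(half = 30, n = 10, z0 = 0, frame = "femoral",
                    normal = c(0, 0, -1))
  for (n in c(10, 40)) {  # default and 4x sampling density
    tib <- make_plate(half = 15, n = n, z0 = 0, frame = "tibial",
                      normal = c(0, 0, 1))
    A <- sum(face_areas(tib$vertices, tib$faces))
    # raise the tibial plate so it penetrates the femoral material by d
    w <- contact_wrench(tib, fem, pose_to_transform(joint_pose(dp = d)), law)
    tol <- if (n == 10) 0.01 else 0.002
    expect_equal(w$axial_force, 30 * d * A, tolerance = tol)
    expect_equal(w$force[3], -30 * d * A, tolerance = tol)
  }
})

test_that("sphere pressed into a plane gives the analytic pole depth", {
  r <- 20; press <- 0.1
  sph <- make_sphere(radius = r, center = c(0, 0, r - press))
  plane <- make_plate(half = 8, n = 16, z0 = 0, frame = "tibial",
                      normal = c(0, 0, 1))
  pf <- penetration_field(plane, sph, pose_to_transform(joint_pose()))
  expect_equal(max(pf$depth), press, tolerance = 0.15)
  # deepest sample sits at the pole
  deepest <- pf$points[which.max(pf$depth), ]
  expect_lt(sqrt(sum(deepest[1:2]^2)), 1.5)
  # swapped roles see the same maximum depth
  sph_t <- sph; sph_t$frame <- "tibial"
  plane_f <- make_plate(half = 8, n = 16, z0 = 0, frame = "femoral",
                        normal = c(0, 0, 1))
  pf2 <- penetration_field(sph_t, plane_f, pose_to_transform(joint_pose()))
  expect_equal(max(pf2$depth), max(pf$depth), tolerance = 0.15)
})

test_that("normal force is monotone in penetration depth", {
  law <- contact_law(friction_mu = 0)
  fem <- make_plate(half = 30, n = 10, z0 = 0, frame = "femoral",
                    normal = c(0, 0, -1))
  tib <- make_plate(half = 15, n = 12, z0 = 0, frame = "tibial",
                    normal = c(0, 0, 1))
  f <- vapply(seq(0, 0.5, by = 0.05), function(dp) {
    contact_wrench(tib, fem, pose_to_transform(joint_pose(dp = dp)),
                   law)$axial_force
  }, 0)
  expect_true(all(diff(f) >= 0))
  expect_gt(f[length(f)], 0)
})

test_that("action equals reaction exactly and friction obeys the cone", {
  surf <- fx_surfaces()
  tr <- pose_to_transform(joint_pose(dp = 0.2, ap = 0.5))
  prev <- pose_to_transform(joint_pose(dp = 0.2))
  law <- contact_law(friction_mu = 0.2)
  pf <- penetration_field(surf$tibial, surf$femoral, tr)
  pen <- pf$depth > 0
  expect_gt(sum(pen), 0)
  # per-sample tangential force never exceeds mu * normal force
  d <- pf$depth[pen]; A <- pf$area[pen]; n <- pf$normal[pen, , drop = FALSE]
  fn <- law$foundation_modulus * d * A
  cen <- face_centroids(surf$tibial$vertices, surf$tibial$faces)
  slip <- (transform_point(tr, cen) - transform_point(prev, cen))[pen, , drop = FALSE]
  slip_t <- slip - n * rowSums(slip * n)
  ft <- sqrt(rowSums(slip_t^2)) * law$friction_mu * fn /
    sqrt(rowSums(slip_t^2) + law$regularization_slip^2)
  expect_true(all(ft <= law$friction_mu * fn + 1e-12))
  # mu = 0 leaves a purely normal wrench; with friction the reaction flips sign
  w0 <- contact_wrench(surf$tibial, surf$femoral, tr, contact_law(friction_mu = 0),
                       prev_transform = prev)
  w1 <- contact_wrench(surf$tibial, surf$femoral, tr, law, prev_transform = prev)
  # the slip here is anterior; friction must oppose it
  expect_lt(w1$force[1], w0$force[1])
})

test_that("contact records tabulate to CSV", {
  surf <- fx_surfaces()
  tr <- pose_to_transform(joint_pose(dp = 0.1))
  w <- contact_wrench(surf$tibial, surf$femoral, tr, contact_law())
  df <- write_contact_csv(list(w, w), tempfile(fileext = ".csv"))
  expect_identical(nrow(df), 2L)
  expect_equal(df$axial_force_N[1], w$axial_force)
})

test_that("meshes are validated and survive STL/OBJ round trips", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  expect_error(implant_surface(v, rbind(c(1, 2, 4)), "femoral"), "degenerate")
  expect_error(implant_surface(v[1:3, ], rbind(c(1, 2, 5)), "femoral"),
               "out of range")
  surf <- make_plate(half = 5, n = 3)
  p1 <- tempfile(fileext = ".stl"); p2 <- tempfile(fileext = ".obj")
  on.exit(unlink(c(p1, p2)))
  write_surface_stl(surf, p1)
  rt <- read_surface_stl(p1, frame = "tibial")
  expect_identical(nrow(rt$faces), nrow(surf$faces))
  expect_equal(sum(face_areas(rt$vertices, rt$faces)),
               sum(face_areas(surf$vertices, surf$faces)))
  write_surface_obj(surf, p2)
  rt2 <- read_surface_obj(p2, frame = "tibial")
  expect_equal(rt2$vertices, unname(surf$vertices))
  expect_equal(rt2$faces, surf$faces)
})
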