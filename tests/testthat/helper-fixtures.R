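# Shared fixtures, memoised so expensive equilibrium sweeps are computed once
# per test session. All fixtures are generated in code; nothing is read from
# disk.

.fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fx_schedule <- function() seq(0, 80, by = 2)

fx_surfaces <- function() fx("surfaces", function() {
  make_implant_surfaces(fixture_spec())
})

fx_apparatus <- function() fx("apparatus", function() make_ligament_set())

fx_law <- function() fx("law", function() contact_law())

fx_curve <- function() fx("curve", function() {
  do.call(compliance_curve, default_compliance_anchors())
})

# near-rigid curve: compliance machinery active but deflections ~1e-9 mm
fx_rigid_curve <- function() fx("rigid_curve", function() {
  compliance_curve(break_load = 500, break_displacement = 1e-9,
                   linear_slope = 1e-12)
})

fx_reference <- function() fx("reference", function() {
  find_reference_pose(fx_apparatus(), fx_surfaces(), fx_law())
})

fx_refcfg <- function(preload = 0, curve = NULL) {
  set_reference_configuration(fx_reference()$pose, preload, curve,
                              fx_apparatus())
}

# ground-truth PCL sweep; scale_1 doubles as the plain reference run
fx_pcl_sweep <- function() fx("pcl_sweep", function() {
  run_pcl_sweep(fx_schedule(), fx_refcfg(), fx_surfaces(), fx_law(),
                scales = c(1, 0.5, 0.25, 0))
})

fx_reference_run <- function() fx_pcl_sweep()$scale_1

fx_emulator_run <- function(preload) {
  nm <- sprintf("emulator_%g", preload)
  fx(nm, function() {
    curve <- fx_curve()
    rc <- fx_refcfg(preload, curve)
    run_passive_flexion(flexion_protocol(fx_schedule(), preload), rc,
                        fx_surfaces(), fx_law(), curve)
  })
}

fx_mean_load <- function() fx("mean_load", function() {
  mean(fx_reference_run()$steps$axial_force_N)
})

fx_emulator_rigid <- function() fx("emulator_rigid", function() {
  curve <- fx_rigid_curve()
  rc <- fx_refcfg(0, curve)
  run_passive_flexion(flexion_protocol(fx_schedule(), 0), rc,
                      fx_surfaces(), fx_law(), curve)
})

# --- small analytic meshes -------------------------------------------------

# square plate triangle mesh in the z = z0 plane; normals along +z or -z
make_plate <- function(half = 20, n = 10, z0 = 0, frame = "tibial",
                       normal = c(0, 0, 1)) {
  xs <- seq(-half, half, length.out = n + 1)
  g <- expand.grid(x = xs, y = xs)
  v <- cbind(g$x, g$y, z0)
  idx <- function(i, j) (j - 1) * (n + 1) + i
  f <- matrix(0L, 2 * n * n, 3)
  k <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      f[k, ] <- c(a, b, c); f[k + 1L, ] <- c(a, c, d)
      k <- k + 2L
    }
  }
  s <- implant_surface(v, f, frame)
  fn <- face_normals(s$vertices, s$faces)
  flip <- fn %*% normal < 0
  s$faces[flip, ] <- s$faces[flip, c(1, 3, 2)]
  s
}

# UV-sphere mesh (closed), outward normals
make_sphere <- function(radius = 20, center = c(0, 0, 0), n_lon = 96,
                        n_lat = 48, frame = "femoral") {
  lat <- seq(0, pi, length.out = n_lat + 1)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1)[-(n_lon + 1)]
  g <- expand.grid(lon = lon, lat = lat)
  v <- cbind(center[1] + radius * sin(g$lat) * cos(g$lon),
             center[2] + radius * sin(g$lat) * sin(g$lon),
             center[3] + radius * cos(g$lat))
  idx <- function(i, j) (j - 1) * n_lon + ((i - 1) %% n_lon) + 1
  f <- list()
  for (j in seq_len(n_lat)) {
    for (i in seq_len(n_lon)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      f[[length(f) + 1L]] <- c(a, b, c)
      f[[length(f) + 1L]] <- c(a, c, d)
    }
  }
  f <- do.call(rbind, f)
  ok <- face_areas(v, f) > 1e-9  # drop degenerate pole slivers
  f <- f[ok, , drop = FALSE]
  s <- implant_surface(v, f, frame)
  cen <- face_centroids(s$vertices, s$faces)
  out <- sweep(cen, 2, center, "-")
  fn <- face_normals(s$vertices, s$faces)
  flip <- rowSums(fn * out) < 0
  s$faces[flip, ] <- s$faces[flip, c(1, 3, 2)]
  s
}

# vertical two-bundle apparatus for analytic wrench checks
make_vertical_bundle <- function(name = "V", y = 0, k = 1000, eps_r = 0.1,
                                 length_ref = 50) {
  ligament_bundle(name, origin = c(0, y, 0),
                  insertion = c(0, y, -length_ref), stiffness_k = k,
                  reference_strain = eps_r)
}
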