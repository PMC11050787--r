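# Synthetic fixtures: implant surfaces, ligament apparatus, compliance
# anchors and the exemplary vertical bundle of the bench experiment.
#
# The implant geometry is a deliberately simple stand-in for a commercial
# bicondylar PCL-retaining fixed-bearing TKR: two toroidal femoral condyle
# patches articulating on two dished (paraboloid) tibial plateau patches.
# Ligament coordinates and stiffnesses are fixture constants chosen to be
# anatomically plausible (collaterals at the epicondyles, PCL central and
# posterior, capsule structures posterior); they stand in for unpublished
# cadaver-derived data and are not claimed to match any implant or specimen.

#' Specification of the synthetic implant fixture
#'
#' @param condyle_core_radius Sagittal core-circle radius of each femoral
#'   condyle torus (mm). The outer sagittal radius is
#'   `condyle_core_radius + condyle_tube_radius`.
#' @param condyle_tube_radius Frontal (tube) radius of each condyle (mm).
#' @param condyle_spacing Medial-lateral distance between condyle centers (mm).
#' @param dish_sagittal_radius,dish_frontal_radius Tibial dish radii of
#'   curvature at the dish bottom (mm); must exceed the corresponding femoral
#'   radii for conforming contact.
#' @param resolution Mesh resolution (grid divisions); each surface must end
#'   up with at least 500 faces.
#' @param seed Seed for the ligament-coordinate jitter.
#' @param jitter Ligament-coordinate jitter amplitude (mm, default 0: exact
#'   fixture constants).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(condyle_core_radius = 15, condyle_tube_radius = 20,
                         condyle_spacing = 44, dish_sagittal_radius = 45,
                         dish_frontal_radius = 24, resolution = 16,
                         seed = 1L, jitter = 0) {
  stopifnot(condyle_core_radius > 0, condyle_tube_radius > 0,
            condyle_spacing > 0, jitter >= 0)
  if (dish_frontal_radius <= condyle_tube_radius ||
      dish_sagittal_radius <= condyle_core_radius + condyle_tube_radius)
    stop("tibial dish radii must exceed femoral condyle radii (conforming contact)")
  structure(list(condyle_core_radius = condyle_core_radius,
                 condyle_tube_radius = condyle_tube_radius,
                 condyle_spacing = condyle_spacing,
                 dish_sagittal_radius = dish_sagittal_radius,
                 dish_frontal_radius = dish_frontal_radius,
                 resolution = resolution, seed = as.integer(seed),
                 jitter = jitter), class = "fixture_spec")
}

# Grid-quad triangulation with winding fixed so face normals align with a
# supplied outward direction field.
.grid_mesh <- function(pts, nu, nv, outward) {
  faces <- NULL
  idx <- function(i, j) (i - 1) * nv + j
  f <- matrix(0L, 2 * (nu - 1) * (nv - 1), 3)
  k <- 1L
  for (i in seq_len(nu - 1)) {
    for (j in seq_len(nv - 1)) {
      a <- idx(i, j); b <- idx(i + 1, j); c <- idx(i + 1, j + 1); d <- idx(i, j + 1)
      f[k, ] <- c(a, b, c); f[k + 1L, ] <- c(a, c, d)
      k <- k + 2L
    }
  }
  n <- face_normals(pts, f)
  cen <- face_centroids(pts, f)
  od <- outward(cen)
  flip <- rowSums(n * od) < 0
  f[flip, ] <- f[flip, c(1, 3, 2)]
  list(vertices = pts, faces = f)
}

#' Generate the articulating implant surfaces
#'
#' Femoral component: two toroidal condyle patches, symmetric about the
#' sagittal plane, with the torus axis on the femoral y (gimbal flexion)
#' axis. Tibial insert: two matching dished plateau patches whose lowest
#' points touch the condyles exactly at the zero pose. Outward normals point
#' out of the component material.
#'
#' @param spec A [fixture_spec()].
#' @return List with `femoral` and `tibial` [implant_surface()] objects.
#' @export
make_implant_surfaces <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  res <- spec$resolution
  cc <- spec$condyle_core_radius
  rt <- spec$condyle_tube_radius
  half <- spec$condyle_spacing / 2

  # femoral: sweep angle phi from the -z axis, positive posterior
  nphi <- round(1.4 * res)
  nw <- round(0.7 * res)
  phi <- seq(-50, 115, length.out = nphi) * pi / 180
  w <- seq(-60, 60, length.out = nw) * pi / 180
  fem_patch <- function(yc) {
    g <- expand.grid(w = w, phi = phi) # v index (w) fastest
    dx <- -sin(g$phi); dz <- -cos(g$phi)
    px <- cc * dx + rt * cos(g$w) * dx
    py <- yc + rt * sin(g$w)
    pz <- cc * dz + rt * cos(g$w) * dz
    pts <- cbind(px, py, pz)
    outward <- function(cen) {
      # away from the local core-circle point
      rho <- sqrt(cen[, 1]^2 + cen[, 3]^2)
      core <- cbind(cc * cen[, 1] / rho, yc, cc * cen[, 3] / rho)
      d <- cen - core
      d / sqrt(rowSums(d^2))
    }
    .grid_mesh(pts, nphi, nw, outward)
  }
  fm <- fem_patch(half)
  fl <- fem_patch(-half)
  fem <- implant_surface(rbind(fm$vertices, fl$vertices),
                         rbind(fm$faces, fl$faces + nrow(fm$vertices)),
                         frame = "femoral")

  # tibial: paraboloid dish per plateau, bottom touching at the zero pose
  z0 <- -(cc + rt)
  nx <- round(1.4 * res)
  ny <- res
  xs <- seq(-16, 16, length.out = nx)
  tib_patch <- function(yc) {
    ys <- seq(yc - 12, yc + 12, length.out = ny)
    g <- expand.grid(y = ys, x = xs)
    pz <- z0 + g$x^2 / (2 * spec$dish_sagittal_radius) +
      (g$y - yc)^2 / (2 * spec$dish_frontal_radius)
    pts <- cbind(g$x, g$y, pz)
    outward <- function(cen) matrix(rep(c(0, 0, 1), each = nrow(cen)), ncol = 3)
    .grid_mesh(pts, nx, ny, outward)
  }
  tm <- tib_patch(half)
  tl <- tib_patch(-half)
  tib <- implant_surface(rbind(tm$vertices, tl$vertices),
                         rbind(tm$faces, tl$faces + nrow(tm$vertices)),
                         frame = "tibial")

  if (nrow(fem$faces) < 500 || nrow(tib$faces) < 500)
    stop("resolution too coarse: each surface needs at least 500 faces")
  list(femoral = fem, tibial = tib)
}

# Fixture constants of the ligament apparatus (mm; femoral frame origin on
# the gimbal flexion axis, joint line near z = -35; x anterior, y medial,
# z proximal, right knee). Stiffnesses in N per unit strain and reference
# strains are plausible stand-ins for cadaver-derived sets.
.LIGAMENT_TABLE <- function() {
  tab <- rbind(
    # name       ox    oy   oz     ix    iy    iz      k    eps_r
    c("MCL_a",     2,  42,   4,     6,   38,  -72,  2750,  0.08),
    c("MCL_m",    -4,  43,   5,     0,   39,  -73,  2750,  0.08),
    c("MCL_p",   -10,  42,   4,    -8,   38,  -72,  2750,  0.08),
    c("LCL_a",     2, -42,   4,     6,  -40,  -62,  2000,  0.08),
    c("LCL_m",    -4, -43,   5,     0,  -41,  -63,  2000,  0.08),
    c("LCL_p",   -10, -42,   4,    -8,  -40,  -62,  2000,  0.08),
    c("opMCL",   -15,  38,   0,   -18,   32,  -45,  1500,  0.05),
    c("dMCL_a",    2,  40,   1,     3,   37,  -42,  2000,  0.04),
    c("dMCL_p",   -8,  40,   1,    -9,   37,  -42,  2000,  0.04),
    c("PCL_al",    7,  -4,  -2,    -8,   -2,  -38,  6000, -0.12),
    c("PCL_pm",    5,   3,  -3,   -10,    3,  -36,  5000, -0.11),
    c("OPL_s",   -22,  -8,  -4,   -24,   10,  -50,  1200,  0.05),
    c("OPL_i",   -22, -14,  -8,   -24,    2,  -52,  1200,  0.05),
    c("APL",     -20, -26,  -4,   -24,  -22,  -48,  1200,  0.05),
    c("mpCAP",   -20,  18,  -2,   -24,   20,  -48,  2500,  0.06),
    c("lpCAP",   -20, -18,  -2,   -24,  -20,  -48,  2500,  0.06))
  data.frame(name = tab[, 1],
             ox = as.numeric(tab[, 2]), oy = as.numeric(tab[, 3]),
             oz = as.numeric(tab[, 4]), ix = as.numeric(tab[, 5]),
             iy = as.numeric(tab[, 6]), iz = as.numeric(tab[, 7]),
             k = as.numeric(tab[, 8]), eps_r = as.numeric(tab[, 9]),
             stringsAsFactors = FALSE)
}

#' Generate the synthetic ligament apparatus
#'
#' Sixteen bundles: 2 PCL, 3 MCL, 3 LCL, 1 opMCL, 2 dMCL, 2 OPL, 1 APL,
#' 1 mpCAP, 1 lpCAP. Collaterals sit at the epicondyles near the flexion
#' axis (near-isometric); posterior capsule structures are pretensioned in
#' extension and slacken with flexion; the PCL is slack in extension and
#' tensions progressively with flexion. The `"symmetric"` variant mirrors
#' the medial structures onto the lateral side with equal stiffness, for
#' symmetry checks.
#'
#' @param variant `"default"` or `"symmetric"`.
#' @param seed Seed for the coordinate jitter.
#' @param jitter Jitter amplitude in mm (default 0: exact constants).
#' @return An uncalibrated [ligament_apparatus()].
#' @export
make_ligament_set <- function(variant = c("default", "symmetric"),
                              seed = 1L, jitter = 0) {
  variant <- match.arg(variant)
  tab <- .LIGAMENT_TABLE()
  if (variant == "symmetric") {
    med <- tab[tab$oy >= 0, ]
    lat <- med
    lat$name <- paste0(med$name, "_mir")
    lat$oy <- -med$oy
    lat$iy <- -med$iy
    tab <- rbind(med, lat)
  }
  if (jitter > 0) {
    state <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(state)) assign(".Random.seed", state, .GlobalEnv))
    set.seed(seed)
    jit <- matrix(stats::rnorm(nrow(tab) * 6, sd = jitter), ncol = 6)
    tab[, c("ox", "oy", "oz", "ix", "iy", "iz")] <-
      tab[, c("ox", "oy", "oz", "ix", "iy", "iz")] + jit
  }
  ligament_apparatus(lapply(seq_len(nrow(tab)), function(i) {
    ligament_bundle(tab$name[i], c(tab$ox[i], tab$oy[i], tab$oz[i]),
                    c(tab$ix[i], tab$iy[i], tab$iz[i]),
                    stiffness_k = tab$k[i], reference_strain = tab$eps_r[i])
  }))
}

#' The exemplary vertical bundle of the bench compliance experiment
#'
#' A single pretensioned fiber on a vertical line of action: stiffness
#' 3300 N per unit strain, 11 percent reference strain, quadratic-to-linear
#' transition at 6 percent strain, rest length 46.5 mm (so the reference
#' insertion distance is 46.5 * 1.11 = 51.615 mm). The rest length is a
#' fixture constant: it is the value at which shortening the fiber by the
#' maximum unsensed deflection of 2.2 mm brings its force to about 108 N,
#' consistent with the bench measurement (a brute-force 1-D solve over rest
#' length reproduces it; see the package tests).
#'
#' @return A calibrated [ligament_bundle()] named `"LCL_ex"`.
#' @export
make_exemplary_lcl_fixture <- function() {
  rest <- 46.5
  eps_r <- 0.11
  ligament_bundle("LCL_ex", origin = c(0, 0, 0),
                  insertion = c(0, 0, -rest * (1 + eps_r)),
                  stiffness_k = 3300, reference_strain = eps_r,
                  linear_limit = 0.03, rest_length = rest)
}

#' Measured compliance anchors of the upper actuator
#'
#' The 0-degree arm-rotation anchors: 0.7 mm deflection at 500 N and a
#' linear gradient of 0.6 mm per 1000 N beyond. The non-zero-angle scale
#' factors are configurable placeholders (compliance decreases with arm
#' rotation; only the 0-degree curve is quantified).
#'
#' @return A list of arguments for [compliance_curve()].
#' @export
default_compliance_anchors <- function() {
  list(break_load = 500, break_displacement = 0.7, linear_slope = 6e-4,
       angle_scale = c("0" = 1.0, "30" = 0.9, "60" = 0.8, "90" = 0.7))
}

#' Generate and write all fixtures to a directory
#'
#' Writes the implant surfaces (STL), the ligament set (YAML) and the
#' compliance anchors (JSON).
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return Named character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surf <- make_implant_surfaces(spec)
  app <- make_ligament_set(seed = spec$seed, jitter = spec$jitter)
  paths <- c(femoral_stl = file.path(dir, "femoral.stl"),
             tibial_stl = file.path(dir, "tibial.stl"),
             ligaments_yaml = file.path(dir, "ligaments.yaml"),
             compliance_json = file.path(dir, "compliance.json"))
  write_surface_stl(surf$femoral, paths["femoral_stl"])
  write_surface_stl(surf$tibial, paths["tibial_stl"])
  write_ligament_yaml(app, paths["ligaments_yaml"])
  write_compliance_json(do.call(compliance_curve, default_compliance_anchors()),
                        paths["compliance_json"])
  invisible(paths)
}
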