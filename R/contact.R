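# Elastic-foundation contact between articulating implant surfaces.
#
# Penetration is sampled at the face centroids of the tibial surface against
# the femoral surface (signed distance via angle-weighted pseudonormals in
# compiled code), with face areas as quadrature weights. Pressure is
# proportional to penetration depth; tangential traction is regularized
# Coulomb friction against the per-step slip of each sample point.

#' Elastic-foundation contact parameters
#'
#' @param foundation_modulus Pressure per unit penetration, N/mm^3
#'   (default 30, the order of a UHMWPE elastic-foundation stiffness).
#' @param friction_mu Coulomb friction coefficient (default 0.04, lubricated
#'   metal-on-polyethylene order of magnitude).
#' @param regularization_slip Slip magnitude (mm per quasi-static step) at
#'   which friction saturates; smooths the Coulomb law (default 0.3, a
#'   fraction of the typical per-step slip so that sustained sliding is
#'   fully developed while slip reversals stay numerically benign).
#' @return An object of class `contact_law`.
#' @export
contact_law <- function(foundation_modulus = 30, friction_mu = 0.04,
                        regularization_slip = 0.3) {
  stopifnot(foundation_modulus > 0, friction_mu >= 0, regularization_slip > 0)
  structure(list(foundation_modulus = foundation_modulus,
                 friction_mu = friction_mu,
                 regularization_slip = regularization_slip),
            class = "contact_law")
}

#' Penetration field of the tibial surface into the femoral surface
#'
#' Tibial face centroids are mapped into the femoral frame by `transform`
#' and queried against the femoral mesh. Penetration depth is the magnitude
#' of the negative signed distance (zero where the surfaces are separated);
#' the contact normal at a penetrating sample is the unit vector from the
#' sample to its closest point on the femoral surface, i.e. the direction of
#' the push the femoral material exerts on the tibial sample.
#'
#' @param tibial_surface,femoral_surface [implant_surface()] objects in their
#'   own component frames.
#' @param transform `rigid_transform` of the tibial frame w.r.t. the femoral
#'   frame.
#' @return List: `depth` (mm, >= 0 per tibial face), `normal` (m x 3, femoral
#'   frame; zero rows where not in contact), `points` (sample positions,
#'   femoral frame), `area` (mm^2 face weights), `signed_distance` (mm).
#' @export
penetration_field <- function(tibial_surface, femoral_surface, transform) {
  stopifnot(inherits(tibial_surface, "implant_surface"),
            inherits(femoral_surface, "implant_surface"))
  cen <- face_centroids(tibial_surface$vertices, tibial_surface$faces)
  p <- transform_point(transform, cen)
  sdres <- mesh_signed_distance_cpp(p, femoral_surface$vertices,
                                    femoral_surface$faces - 1L)
  sd <- sdres$signed_distance
  depth <- pmax(0, -sd)
  normal <- matrix(0, nrow(p), 3)
  pen <- depth > 0
  if (any(pen)) {
    d <- sdres$closest[pen, , drop = FALSE] - p[pen, , drop = FALSE]
    normal[pen, ] <- d / sqrt(rowSums(d^2))
  }
  list(depth = depth, normal = normal, points = p,
       area = face_areas(tibial_surface$vertices, tibial_surface$faces),
       signed_distance = sd)
}

#' Contact wrench on the tibial component
#'
#' Integrates elastic-foundation pressure and regularized Coulomb friction
#' over the penetrating tibial samples. The reaction on the femoral component
#' is the exact negative.
#'
#' @inheritParams penetration_field
#' @param law A [contact_law()].
#' @param moment_reference_point 3-vector, mm, femoral frame.
#' @param prev_transform Optional `rigid_transform` of the previous
#'   quasi-static step; per-sample slip for the friction model is the motion
#'   of each tibial sample point since that step. With `NULL`, friction is
#'   omitted (pure normal contact).
#' @return List: `force` (N), `moment` (N mm) on the tibial component in the
#'   femoral frame; `axial_force` (N, positive in compression) along the
#'   tibial mechanical axis; `max_depth` (mm); `contact_area` (mm^2);
#'   `n_contact` (number of penetrating samples).
#' @export
contact_wrench <- function(tibial_surface, femoral_surface, transform, law,
                           moment_reference_point = c(0, 0, 0),
                           prev_transform = NULL) {
  pf <- penetration_field(tibial_surface, femoral_surface, transform)
  pen <- pf$depth > 0
  if (!any(pen)) {
    return(list(force = c(0, 0, 0), moment = c(0, 0, 0), axial_force = 0,
                max_depth = 0, contact_area = 0, n_contact = 0L))
  }
  d <- pf$depth[pen]
  A <- pf$area[pen]
  n <- pf$normal[pen, , drop = FALSE]
  pts <- pf$points[pen, , drop = FALSE]
  fn_mag <- law$foundation_modulus * d * A
  Fsamp <- n * fn_mag

  if (!is.null(prev_transform) && law$friction_mu > 0) {
    cen <- face_centroids(tibial_surface$vertices, tibial_surface$faces)
    slip <- (transform_point(transform, cen) -
               transform_point(prev_transform, cen))[pen, , drop = FALSE]
    slip_t <- slip - n * rowSums(slip * n)
    smag <- sqrt(rowSums(slip_t^2))
    scale <- law$friction_mu * fn_mag /
      sqrt(smag^2 + law$regularization_slip^2)
    Fsamp <- Fsamp - slip_t * scale
  }

  force <- colSums(Fsamp)
  r <- sweep(pts, 2, moment_reference_point, "-")
  moment <- c(sum(r[, 2] * Fsamp[, 3] - r[, 3] * Fsamp[, 2]),
              sum(r[, 3] * Fsamp[, 1] - r[, 1] * Fsamp[, 3]),
              sum(r[, 1] * Fsamp[, 2] - r[, 2] * Fsamp[, 1]))
  tib_axis <- transform$R[, 3]
  list(force = force, moment = moment,
       axial_force = -sum(force * tib_axis),
       max_depth = max(d), contact_area = sum(A), n_contact = sum(pen))
}

#' Summarize per-step contact to CSV
#'
#' @param records A list of `contact_wrench()` results.
#' @param path Output CSV path.
#' @return The summary data frame, invisibly written to `path`.
#' @export
write_contact_csv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(w) {
    data.frame(fx_N = w$force[1], fy_N = w$force[2], fz_N = w$force[3],
               mx_Nmm = w$moment[1], my_Nmm = w$moment[2], mz_Nmm = w$moment[3],
               axial_force_N = w$axial_force, max_depth_mm = w$max_depth,
               contact_area_mm2 = w$contact_area, n_contact = w$n_contact)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
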