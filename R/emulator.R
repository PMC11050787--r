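# Joint-simulator emulation: reference configuration under preload, sensed
# (compliance-corrupted) poses, and the passive flexion protocol.
#
# The machine defines ligament insertion points at a reference configuration
# set under a chosen vertical preload. During a test the upper actuator
# deflects by delta(F), unsensed; the ligament force calculation therefore
# sees a pose that is shifted along the distal-proximal axis by
# delta(F) - delta(preload) relative to the true pose. Contact always acts
# at the true pose. With F equal to the preload, the sensed and true poses
# coincide: that is the compensation point.

#' Reference configuration for a simulator test
#'
#' Calibrates every bundle's rest length at the (0-degree flexion) reference
#' pose and stores the actuator deflection at the chosen preload, which is
#' the deflection already present when the insertion points are defined.
#'
#' @param reference_pose [joint_pose()] at 0 degrees flexion, usually the
#'   ground-truth model's equilibrium (see [find_reference_pose()]).
#' @param preload Vertical contact force (N, >= 0) applied while the
#'   reference configuration is set. A value near the mean load of the
#'   planned cycle approximately compensates the compliance artifact.
#' @param compliance_curve A [compliance_curve()], or `NULL` for a rigid
#'   simulator (reference deflection 0).
#' @param apparatus A [ligament_apparatus()] (calibrated here).
#' @return An object of class `reference_configuration` with fields
#'   `reference_pose`, `preload`, `reference_deflection` (mm) and the
#'   calibrated `apparatus`.
#' @export
set_reference_configuration <- function(reference_pose, preload,
                                        compliance_curve, apparatus) {
  stopifnot(preload >= 0)
  delta_ref <- if (is.null(compliance_curve)) 0 else
    displacement_at_load(compliance_curve, preload, arm_angle = 0)
  apparatus <- calibrate_apparatus(apparatus, pose_to_transform(reference_pose))
  structure(list(reference_pose = reference_pose, preload = preload,
                 reference_deflection = delta_ref, apparatus = apparatus),
            class = "reference_configuration")
}

#' Sensed pose implied by unsensed actuator deflection
#'
#' The sensed pose differs from the true pose only by a distal-proximal
#' shift of `delta(F) - delta_ref`: under loads above the preload the
#' components appear closer together (virtual ligaments shortened), below
#' it further apart.
#'
#' @param true_pose The true [joint_pose()].
#' @param contact_axial_force Axial contact force F in N (negative values
#'   are treated as zero load).
#' @param compliance_curve A [compliance_curve()], or `NULL` for a rigid
#'   simulator (sensed equals true).
#' @param reference_deflection Deflection delta_ref (mm) stored in the
#'   reference configuration.
#' @return The sensed [joint_pose()].
#' @export
sensed_pose_from_true <- function(true_pose, contact_axial_force,
                                  compliance_curve, reference_deflection = 0) {
  if (is.null(compliance_curve)) return(true_pose)
  delta <- displacement_at_load(compliance_curve,
                                max(0, contact_axial_force), arm_angle = 0)
  .pose_set(true_pose, "dp", true_pose$dp + (delta - reference_deflection))
}

#' Prescribed passive flexion protocol
#'
#' @param schedule Monotone flexion schedule in degrees with steps of at
#'   most 2 degrees (default 0 to 80 in 1-degree steps).
#' @param preload Reference-configuration vertical force in N.
#' @param free_dofs Force-controlled coordinates (default: all five
#'   non-flexion DOFs). Flexion is always position-controlled.
#' @return An object of class `flexion_protocol`.
#' @export
flexion_protocol <- function(schedule = seq(0, 80, by = 1), preload = 800,
                             free_dofs = c("adduction", "internal",
                                           "ap", "ml", "dp")) {
  stopifnot(length(schedule) >= 1, preload >= 0,
            all(free_dofs %in% setdiff(.POSE_COORDS, "flexion")))
  if (length(schedule) > 1) {
    d <- diff(schedule)
    if (any(d <= 0)) stop("flexion schedule must be strictly increasing")
    if (any(d > 2)) stop("flexion schedule steps must be <= 2 degrees")
  }
  structure(list(schedule = schedule, preload = preload,
                 free_dofs = free_dofs), class = "flexion_protocol")
}

# Residual of one quasi-static step. Contact (normal + regularized friction
# against the previous-step slip anchor) acts at the true pose; the applied
# ligament wrench is evaluated at the sensed pose implied by the axial
# contact force. With compliance_curve = NULL this is the ground-truth model
# (sensed == true).
.step_residual_fn <- function(apparatus, surfaces, law, compliance_curve,
                              refcfg, free_dofs, prev_transform) {
  delta_ref <- if (is.null(refcfg)) 0 else refcfg$reference_deflection
  function(pose) {
    tr <- pose_to_transform(pose)
    cw <- contact_wrench(surfaces$tibial, surfaces$femoral, tr, law,
                         prev_transform = prev_transform)
    if (is.null(compliance_curve)) {
      shift <- 0
      tr_sensed <- tr
      sensed_pose <- pose
    } else {
      delta <- displacement_at_load(compliance_curve, max(0, cw$axial_force))
      shift <- delta - delta_ref
      sensed_pose <- .pose_set(pose, "dp", pose$dp + shift)
      tr_sensed <- pose_to_transform(sensed_pose)
    }
    lw <- apparatus_wrench(apparatus, tr_sensed)
    Q <- .generalized_forces(pose, free_dofs, list(cw, lw))
    list(Q = Q, contact = cw, ligament = lw, deflection_shift = shift,
         sensed_pose = sensed_pose, transform = tr)
  }
}

#' Solve the quasi-static equilibrium at one flexion angle
#'
#' Finds the true pose at which the generalized forces of the contact wrench
#' (true pose) plus the applied ligament wrench (sensed pose) vanish on the
#' force-controlled DOFs.
#'
#' @param flexion_deg Prescribed flexion angle (degrees).
#' @param previous_pose Warm-start [joint_pose()] (e.g. previous step).
#' @param apparatus Calibrated [ligament_apparatus()] (usually
#'   `refcfg$apparatus`).
#' @param surfaces List with `femoral` and `tibial` [implant_surface()].
#' @param law A [contact_law()].
#' @param compliance_curve A [compliance_curve()] or `NULL` (rigid).
#' @param refcfg A `reference_configuration` (or `NULL` for zero reference
#'   deflection).
#' @param prev_transform Previous-step `rigid_transform` used as the slip
#'   anchor of the friction model (`NULL`: frictionless step).
#' @param free_dofs Force-controlled coordinates.
#' @param tol_force,tol_moment Convergence tolerances (N, N mm).
#' @param max_iter Newton iteration cap.
#' @return List: `pose` (true), `sensed_pose`, `converged`, `iterations`,
#'   `residual` (generalized forces), `contact`, `ligament` (sensed
#'   apparatus wrench), `ligament_true` (apparatus wrench at the true pose),
#'   `deflection_shift` (mm), `lost_contact`.
#' @export
solve_step_equilibrium <- function(flexion_deg, previous_pose, apparatus,
                                   surfaces, law, compliance_curve = NULL,
                                   refcfg = NULL, prev_transform = NULL,
                                   free_dofs = c("adduction", "internal",
                                                 "ap", "ml", "dp"),
                                   tol_force = 0.5, tol_moment = 50,
                                   max_iter = 50) {
  pose0 <- .pose_set(previous_pose, "flexion", flexion_deg)
  rf <- .step_residual_fn(apparatus, surfaces, law, compliance_curve, refcfg,
                          free_dofs, prev_transform)
  sol <- .newton_equilibrium(rf, pose0, free_dofs, tol_force, tol_moment,
                             max_iter)
  ex <- sol$extras
  lost <- ex$contact$n_contact == 0L
  if (lost) warning("loss of contact at flexion ", flexion_deg, " deg")
  lig_true <- apparatus_wrench(apparatus, ex$transform)
  list(pose = sol$pose, sensed_pose = ex$sensed_pose,
       converged = sol$converged, iterations = sol$iterations,
       residual = sol$residual, contact = ex$contact, ligament = ex$ligament,
       ligament_true = lig_true, deflection_shift = ex$deflection_shift,
       lost_contact = lost)
}

# Continuation engine shared by the emulator and the ground-truth model.
# Warm starts each scheduled angle from the previous solution; on
# non-convergence the interval is bisected down to 0.25-degree substeps.
.run_flexion <- function(schedule, apparatus, surfaces, law, compliance_curve,
                         refcfg, free_dofs, tol_force = 0.5, tol_moment = 50,
                         max_iter = 50, friction_memory = TRUE) {
  pose <- refcfg$reference_pose
  prev_tr <- NULL
  nstep <- length(schedule)
  nb <- length(apparatus$bundles)
  steps <- data.frame(flexion_deg = schedule, axial_force_N = NA_real_,
                      tibial_ie_deg = NA_real_, femoral_ap_mm = NA_real_,
                      adduction_deg = NA_real_, ml_mm = NA_real_,
                      dp_mm = NA_real_, deflection_mm = NA_real_,
                      lig_force_sensed_N = NA_real_,
                      lig_force_true_N = NA_real_,
                      residual_force_N = NA_real_,
                      residual_moment_Nmm = NA_real_, converged = NA)
  bundle_sensed <- matrix(NA_real_, nstep, nb,
                          dimnames = list(NULL, names(apparatus$bundles)))
  bundle_true <- bundle_sensed
  poses <- vector("list", nstep)
  ref_pose <- refcfg$reference_pose

  solve_to <- function(target, pose, prev_tr, depth = 0) {
    sol <- solve_step_equilibrium(target, pose, apparatus, surfaces, law,
                                  compliance_curve, refcfg, prev_tr,
                                  free_dofs, tol_force, tol_moment, max_iter)
    if (sol$converged || depth >= 4 ||
        (target - pose$flexion) <= 0.25) return(sol)
    mid <- (pose$flexion + target) / 2
    half <- solve_to(mid, pose, prev_tr, depth + 1)
    solve_to(target, half$pose,
             if (friction_memory) pose_to_transform(half$pose) else prev_tr,
             depth + 1)
  }

  for (i in seq_len(nstep)) {
    sol <- solve_to(schedule[i], pose, prev_tr)
    pose <- sol$pose
    if (friction_memory) prev_tr <- pose_to_transform(pose)
    ang <- free_dofs %in% .ANGLE_COORDS
    steps$axial_force_N[i] <- sol$contact$axial_force
    steps$tibial_ie_deg[i] <- pose$internal - ref_pose$internal
    steps$femoral_ap_mm[i] <- -(pose$ap - ref_pose$ap)
    steps$adduction_deg[i] <- pose$adduction - ref_pose$adduction
    steps$ml_mm[i] <- pose$ml - ref_pose$ml
    steps$dp_mm[i] <- pose$dp - ref_pose$dp
    steps$deflection_mm[i] <- sol$deflection_shift
    steps$lig_force_sensed_N[i] <- sum(sol$ligament$magnitudes)
    steps$lig_force_true_N[i] <- sum(sol$ligament_true$magnitudes)
    steps$residual_force_N[i] <- max(abs(sol$residual[!ang]), 0)
    steps$residual_moment_Nmm[i] <- max(abs(sol$residual[ang]), 0)
    steps$converged[i] <- sol$converged
    bundle_sensed[i, ] <- sol$ligament$magnitudes
    bundle_true[i, ] <- sol$ligament_true$magnitudes
    poses[[i]] <- pose
    if (!sol$converged && i > 1 && !steps$converged[i - 1]) {
      warning("aborting sweep after repeated non-convergence at ",
              schedule[i], " deg; returning partial result")
      steps <- steps[seq_len(i), ]
      bundle_sensed <- bundle_sensed[seq_len(i), , drop = FALSE]
      bundle_true <- bundle_true[seq_len(i), , drop = FALSE]
      poses <- poses[seq_len(i)]
      break
    }
  }

  structure(list(steps = steps, bundle_sensed = bundle_sensed,
                 bundle_true = bundle_true, poses = poses,
                 reference_pose = ref_pose,
                 compliance = !is.null(compliance_curve),
                 preload = refcfg$preload), class = "flexion_result")
}

#' Run the passive flexion protocol on the emulated simulator
#'
#' Position-controls flexion along the protocol schedule while the remaining
#' DOFs settle into quasi-static equilibrium between the true-pose contact
#' wrench and the sensed-pose ligament wrench. Kinematic outputs are
#' reported relative to the reference configuration at 0 degrees flexion;
#' femoral AP displacement is the negated tibial AP coordinate.
#'
#' @param protocol A [flexion_protocol()].
#' @param refcfg A [set_reference_configuration()] result (carries the
#'   calibrated apparatus and the reference deflection).
#' @param surfaces List with `femoral` and `tibial` [implant_surface()].
#' @param law A [contact_law()].
#' @param compliance_curve A [compliance_curve()]; `NULL` emulates a
#'   perfectly rigid simulator.
#' @param apparatus Optional apparatus overriding `refcfg$apparatus`
#'   (e.g. after [set_resection()]).
#' @param tol_force,tol_moment,max_iter Solver controls.
#' @return A `flexion_result`: data frame `steps` (per-angle axial force,
#'   referenced kinematics, deflection, total sensed/true ligament force,
#'   force and moment residuals, convergence flag), matrices `bundle_sensed`
#'   / `bundle_true` (per-bundle forces, N), and the solved `poses`.
#' @export
run_passive_flexion <- function(protocol, refcfg, surfaces, law,
                                compliance_curve, apparatus = NULL,
                                tol_force = 0.5, tol_moment = 50,
                                max_iter = 50) {
  stopifnot(inherits(protocol, "flexion_protocol"),
            inherits(refcfg, "reference_configuration"))
  app <- if (is.null(apparatus)) refcfg$apparatus else apparatus
  .run_flexion(protocol$schedule, app, surfaces, law, compliance_curve,
               refcfg, protocol$free_dofs, tol_force, tol_moment, max_iter)
}

#' @export
print.flexion_result <- function(x, ...) {
  cat(sprintf(
    "flexion_result: %d steps, %.0f-%.0f deg, compliance %s, preload %.0f N\n",
    nrow(x$steps), min(x$steps$flexion_deg), max(x$steps$flexion_deg),
    if (x$compliance) "on" else "off", x$preload))
  cat(sprintf("  axial force %.0f N at %.0f deg -> %.0f N at %.0f deg; %d/%d converged\n",
              x$steps$axial_force_N[1], x$steps$flexion_deg[1],
              x$steps$axial_force_N[nrow(x$steps)],
              x$steps$flexion_deg[nrow(x$steps)],
              sum(x$steps$converged), nrow(x$steps)))
  invisible(x)
}

#' Write a flexion result to CSV
#'
#' Columns as in the `steps` data frame; per-bundle sensed/true forces are
#' appended as `sensed_<name>` / `true_<name>` columns.
#'
#' @param result A `flexion_result`.
#' @param path Output CSV path.
#' @param bundles Include per-bundle force columns (default TRUE).
#' @return `path`, invisibly.
#' @export
write_flexion_csv <- function(result, path, bundles = TRUE) {
  df <- result$steps
  if (bundles) {
    bs <- as.data.frame(result$bundle_sensed)
    names(bs) <- paste0("sensed_", names(bs))
    bt <- as.data.frame(result$bundle_true)
    names(bt) <- paste0("true_", names(bt))
    df <- cbind(df, bs, bt)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Worked example: sensed ligament force of a vertical fiber under load
#'
#' Reproduces the bench experiment: a single pretensioned vertical virtual
#' ligament between the actuators while the vertical contact force is ramped
#' up. The unsensed deflection shortens the computed fiber length by
#' `s1(F)`, so the sensed force falls with load even though nothing moves.
#'
#' @param bundle A calibrated vertical [ligament_bundle()] (see
#'   [make_exemplary_lcl_fixture()]).
#' @param compliance_curve A [compliance_curve()]; `NULL` gives the rigid
#'   (constant-force) reference.
#' @param load_grid Vertical loads F in N.
#' @param reference_deflection delta_ref in mm (default 0: no preload
#'   compensation in the bench setup).
#' @return Data frame with `load_N`, `s1_mm`, `strain`, `force_N`.
#' @export
worked_example_force_vs_load <- function(bundle, compliance_curve,
                                         load_grid = seq(0, 3000, by = 10),
                                         reference_deflection = 0) {
  if (is.na(bundle$rest_length)) stop("bundle must be calibrated")
  L_ref <- bundle$rest_length * (1 + bundle$reference_strain)
  s1 <- if (is.null(compliance_curve)) rep(0, length(load_grid)) else
    displacement_at_load(compliance_curve, load_grid) - reference_deflection
  len <- L_ref - s1
  strain <- len / bundle$rest_length - 1
  data.frame(load_N = load_grid, s1_mm = s1, strain = strain,
             force_N = bundle$stiffness_scale *
               force_from_strain(strain, bundle$stiffness_k,
                                 bundle$linear_limit))
}
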