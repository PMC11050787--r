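# Ground-truth quasi-static knee model.
#
# The rigid analogue of a multibody simulation: the femur is fixed, the tibia
# carries five free DOFs while flexion is prescribed, and the equilibrium of
# true-pose ligament and contact wrenches determines the remaining
# coordinates. Identical machinery to the emulator, minus the sensed-pose
# compliance term, so the two are directly comparable.

#' Solve the ground-truth equilibrium at one flexion angle
#'
#' [solve_step_equilibrium()] with the sensed pose identical to the true
#' pose (no compliance term).
#'
#' @inheritParams solve_step_equilibrium
#' @return As [solve_step_equilibrium()]; `ligament` and `ligament_true`
#'   coincide.
#' @export
solve_reference_equilibrium <- function(flexion_deg, previous_pose, apparatus,
                                        surfaces, law, prev_transform = NULL,
                                        free_dofs = c("adduction", "internal",
                                                      "ap", "ml", "dp"),
                                        tol_force = 0.5, tol_moment = 50,
                                        max_iter = 50) {
  solve_step_equilibrium(flexion_deg, previous_pose, apparatus, surfaces, law,
                         compliance_curve = NULL, refcfg = NULL,
                         prev_transform = prev_transform,
                         free_dofs = free_dofs, tol_force = tol_force,
                         tol_moment = tol_moment, max_iter = max_iter)
}

#' Self-consistent reference pose at full extension
#'
#' The reference configuration is the 0-degree-flexion equilibrium of the
#' joint under its ligament apparatus. Because bundle rest lengths are
#' themselves defined at that configuration, the pose is found by fixed-point
#' iteration: calibrate the apparatus at the current pose estimate, solve the
#' equilibrium, repeat until the pose is stationary.
#'
#' @param apparatus An (uncalibrated) [ligament_apparatus()].
#' @param surfaces List with `femoral` and `tibial` [implant_surface()].
#' @param law A [contact_law()].
#' @param initial_pose Optional starting [joint_pose()]; by default the
#'   tibia is lowered onto the femoral component until contact just engages.
#' @param free_dofs Force-controlled coordinates.
#' @param tol Pose fixed-point tolerance (mm / deg).
#' @param max_outer Outer iteration cap.
#' @return List: `pose` (the reference [joint_pose()]), `apparatus`
#'   (calibrated at that pose), `solution` (final equilibrium record).
#' @export
find_reference_pose <- function(apparatus, surfaces, law, initial_pose = NULL,
                                free_dofs = c("adduction", "internal",
                                              "ap", "ml", "dp"),
                                tol = 1e-3, max_outer = 15) {
  if (is.null(initial_pose)) {
    pose <- joint_pose()
    for (dp in seq(-3, 3, by = 0.1)) {
      pf <- penetration_field(surfaces$tibial, surfaces$femoral,
                              pose_to_transform(.pose_set(pose, "dp", dp)))
      if (max(pf$depth) > 0.01) {
        pose <- .pose_set(pose, "dp", dp)
        break
      }
    }
    initial_pose <- pose
  }
  pose <- .pose_set(initial_pose, "flexion", 0)
  sol <- NULL
  app <- apparatus
  for (k in seq_len(max_outer)) {
    app <- calibrate_apparatus(apparatus, pose_to_transform(pose))
    sol <- solve_reference_equilibrium(0, pose, app, surfaces, law,
                                       free_dofs = free_dofs)
    delta <- max(abs(unlist(sol$pose)[.POSE_COORDS] -
                       unlist(pose)[.POSE_COORDS]))
    pose <- sol$pose
    if (delta < tol) break
  }
  list(pose = pose, apparatus = app, solution = sol)
}

#' Run a passive flexion sweep of the ground-truth model
#'
#' @param schedule Monotone flexion schedule (deg, steps <= 2).
#' @param refcfg A [set_reference_configuration()] result; only the
#'   reference pose and calibrated apparatus are used (no compliance).
#' @param surfaces,law As elsewhere.
#' @param apparatus Optional apparatus override (e.g. after
#'   [set_resection()]).
#' @param tol_force,tol_moment,max_iter Solver controls.
#' @return A `flexion_result` with sensed and true ligament forces equal.
#' @export
run_reference_flexion <- function(schedule, refcfg, surfaces, law,
                                  apparatus = NULL, tol_force = 0.5,
                                  tol_moment = 50, max_iter = 50) {
  app <- if (is.null(apparatus)) refcfg$apparatus else apparatus
  .run_flexion(schedule, app, surfaces, law, compliance_curve = NULL,
               refcfg = refcfg,
               free_dofs = c("adduction", "internal", "ap", "ml", "dp"),
               tol_force = tol_force, tol_moment = tol_moment,
               max_iter = max_iter)
}

#' Virtual PCL resection sweep
#'
#' Re-runs an identical flexion sweep with the stiffness of all
#' `prefix`-named bundles scaled by each value in `scales`; every other
#' parameter (calibration, contact, schedule) is bit-identical across runs.
#'
#' @param schedule Flexion schedule (deg).
#' @param refcfg A [set_reference_configuration()] result.
#' @param surfaces,law As elsewhere.
#' @param scales Stiffness scales, e.g. `c(1, 0.5, 0.25, 0)`.
#' @param prefix Bundle-name prefix to scale (default `"PCL"`).
#' @param compliance_curve `NULL` for the ground-truth model (default), or a
#'   [compliance_curve()] to sweep the emulated simulator instead.
#' @param ... Passed to the underlying run function.
#' @return Named list of `flexion_result`, one per scale.
#' @export
run_pcl_sweep <- function(schedule, refcfg, surfaces, law,
                          scales = c(1, 0.5, 0.25, 0), prefix = "PCL",
                          compliance_curve = NULL, ...) {
  res <- lapply(scales, function(s) {
    app <- set_resection(refcfg$apparatus, prefix, s)
    if (is.null(compliance_curve)) {
      run_reference_flexion(schedule, refcfg, surfaces, law,
                            apparatus = app, ...)
    } else {
      proto <- flexion_protocol(schedule, preload = refcfg$preload)
      run_passive_flexion(proto, refcfg, surfaces, law, compliance_curve,
                          apparatus = app, ...)
    }
  })
  names(res) <- sprintf("scale_%g", scales)
  res
}
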