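# Structural compliance of the upper actuator.
#
# Under vertical contact load the gimbal arm structure deflects elastically;
# the deflection is not captured by the joint-coordinate sensors. Measured
# load-deflection curves increase degressively up to a break load and nearly
# linearly beyond it. The model is a power law below the break load whose
# exponent is fixed by C1 continuity with the linear branch above it:
#   s(F) = s_b (F / F_b)^p          for F <= F_b,   p = m F_b / s_b
#   s(F) = s_b + m (F - F_b)        for F  > F_b
# Arm-angle dependence is a multiplicative factor (1.0 at 0 degrees, where
# compliance is maximal; the non-0 factors are configurable placeholders).

#' Calibrate the actuator compliance curve
#'
#' @param break_load Break load F_b in N (default 500).
#' @param break_displacement Deflection s_b at the break load in mm
#'   (default 0.7, the measured 0-degree arm-rotation value).
#' @param linear_slope Slope m of the linear branch in mm per N
#'   (default 6e-4, i.e. 0.6 mm per 1000 N).
#' @param angle_scale Named numeric vector mapping flexion-arm angle (deg)
#'   to a multiplicative deflection factor in (0, 1]. Only the 0-degree
#'   anchors are measured; the other defaults are placeholders.
#' @return An object of class `compliance_curve` with the derived shape
#'   exponent `p = linear_slope * break_load / break_displacement`.
#' @export
#' @examples
#' cc <- compliance_curve()
#' displacement_at_load(cc, 3000) # 0.7 + 6e-4 * 2500 = 2.2 mm
compliance_curve <- function(break_load = 500, break_displacement = 0.7,
                             linear_slope = 6e-4,
                             angle_scale = c("0" = 1.0, "30" = 0.9,
                                             "60" = 0.8, "90" = 0.7)) {
  if (break_load <= 0 || break_displacement <= 0 || linear_slope <= 0)
    stop("compliance anchors must be positive")
  if (any(angle_scale <= 0) || any(angle_scale > 1))
    stop("angle_scale factors must lie in (0, 1]")
  p <- linear_slope * break_load / break_displacement
  structure(list(break_load = break_load,
                 break_displacement = break_displacement,
                 linear_slope = linear_slope,
                 shape_exponent = p,
                 angle_scale = angle_scale),
            class = "compliance_curve")
}

#' @export
print.compliance_curve <- function(x, ...) {
  cat(sprintf(
    "compliance_curve: s_b %.3f mm at F_b %.0f N, slope %.2f mm/1000 N, exponent p = %.4f\n",
    x$break_displacement, x$break_load, 1000 * x$linear_slope, x$shape_exponent))
  invisible(x)
}

.angle_factor <- function(curve, arm_angle) {
  ang <- as.numeric(names(curve$angle_scale))
  if (length(ang) == 1) return(unname(curve$angle_scale))
  a <- min(max(arm_angle, min(ang)), max(ang))
  approx(ang, curve$angle_scale, xout = a)$y
}

#' Unsensed actuator deflection at a vertical load
#'
#' @param curve A [compliance_curve()].
#' @param load Vertical force F in N (>= 0, vectorized).
#' @param arm_angle Flexion-arm angle in degrees (default 0); interpolated
#'   between stored angle factors.
#' @return Deflection s in mm.
#' @export
displacement_at_load <- function(curve, load, arm_angle = 0) {
  if (any(load < 0)) stop("load must be >= 0")
  fac <- .angle_factor(curve, arm_angle)
  s <- ifelse(load <= curve$break_load,
              curve$break_displacement *
                (load / curve$break_load)^curve$shape_exponent,
              curve$break_displacement +
                curve$linear_slope * (load - curve$break_load))
  fac * s
}

#' Inverse compliance curve: load producing a given deflection
#'
#' @param curve A [compliance_curve()].
#' @param displacement Deflection s in mm (>= 0, vectorized).
#' @param arm_angle Flexion-arm angle in degrees (default 0).
#' @return Load F in N such that
#'   `displacement_at_load(curve, F, arm_angle) == displacement`.
#' @export
load_at_displacement <- function(curve, displacement, arm_angle = 0) {
  if (any(displacement < 0)) stop("displacement must be >= 0")
  fac <- .angle_factor(curve, arm_angle)
  s <- displacement / fac
  ifelse(s <= curve$break_displacement,
         curve$break_load *
           (s / curve$break_displacement)^(1 / curve$shape_exponent),
         curve$break_load + (s - curve$break_displacement) / curve$linear_slope)
}

#' Tabulate the compliance curve for plotting
#'
#' @param curve A [compliance_curve()].
#' @param loads Load grid in N.
#' @param arm_angles Arm angles in degrees.
#' @param path Optional CSV output path.
#' @return A data frame with `load_N`, `arm_angle_deg`, `displacement_mm`.
#' @export
compliance_table <- function(curve, loads = seq(0, 3000, by = 50),
                             arm_angles = 0, path = NULL) {
  df <- do.call(rbind, lapply(arm_angles, function(a) {
    data.frame(load_N = loads, arm_angle_deg = a,
               displacement_mm = displacement_at_load(curve, loads, a))
  }))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}

#' Serialize a compliance curve to JSON
#'
#' @param curve A [compliance_curve()].
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
write_compliance_json <- function(curve, path = NULL) {
  obj <- unclass(curve)
  obj$angle_scale <- as.list(obj$angle_scale)
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_compliance_json
#' @export
read_compliance_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  compliance_curve(obj$break_load, obj$break_displacement, obj$linear_slope,
                   unlist(obj$angle_scale))
}
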