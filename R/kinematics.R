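# Six-coordinate tibiofemoral kinematics.
#
# Frame convention (right knee): femoral frame with x anterior, y medial,
# z proximal; the femoral y axis is the gimbal flexion axis. The tibial frame
# coincides with the femoral frame at the zero pose; its z axis is the
# mechanical tibial axis (orthogonal to the mounting plate). Rotation sequence
# is Grood-Suntay style: flexion about the femoral y axis, adduction about the
# rotated (floating) anterior axis, internal rotation about the tibial z axis.
# Translations (ap anterior+, ml medial+, dp proximal+) are expressed in the
# tibial frame, so dp always acts along the tibial mechanical axis.

#' Six-coordinate relative pose of the tibial component
#'
#' @param flexion,adduction,internal Rotations in degrees (see Details).
#' @param ap,ml,dp Translations in mm: anterior, medial and proximal positive.
#'
#' @details Positive flexion rotates the tibia posteriorly about the femoral
#' gimbal (medial-lateral) axis; positive adduction rotates about the floating
#' anterior axis; positive internal rotation turns the tibia about its own
#' mechanical axis (tibial tuberosity moving medially for a right knee).
#' Translations are expressed in the tibial frame, so `dp` is always a shift
#' along the mechanical tibial axis. At the zero pose the frames coincide.
#'
#' @return An object of class `joint_pose`.
#' @export
#' @examples
#' p <- joint_pose(flexion = 30, dp = 2)
#' pose_to_transform(p)
joint_pose <- function(flexion = 0, adduction = 0, internal = 0,
                       ap = 0, ml = 0, dp = 0) {
  vals <- c(flexion = flexion, adduction = adduction, internal = internal,
            ap = ap, ml = ml, dp = dp)
  if (!all(is.finite(vals))) stop("joint_pose coordinates must be finite")
  structure(as.list(vals), class = "joint_pose")
}

#' @export
print.joint_pose <- function(x, ...) {
  cat(sprintf(
    "joint_pose: flex %.2f deg, add %.2f deg, int %.2f deg, ap %.2f mm, ml %.2f mm, dp %.2f mm\n",
    x$flexion, x$adduction, x$internal, x$ap, x$ml, x$dp))
  invisible(x)
}

.rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
.rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
.rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rigid transform of the tibial frame with respect to the femoral frame
#'
#' Maps coordinates of a point fixed in the tibial frame into the femoral
#' frame: `x_fem = R x_tib + t`.
#'
#' @param pose A [joint_pose()].
#' @return A list with class `rigid_transform`: rotation matrix `R` (3x3,
#'   orthonormal, det +1) and translation `t` (mm).
#' @export
pose_to_transform <- function(pose) {
  d2r <- pi / 180
  R <- .rot_y(pose$flexion * d2r) %*% .rot_x(pose$adduction * d2r) %*%
    .rot_z(pose$internal * d2r)
  t <- as.numeric(R %*% c(pose$ap, pose$ml, pose$dp))
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' Recover the six pose coordinates from a rigid transform
#'
#' Inverse of [pose_to_transform()] away from gimbal lock
#' (|adduction| < 90 degrees).
#'
#' @param transform A `rigid_transform`.
#' @return A [joint_pose()].
#' @export
transform_to_pose <- function(transform) {
  R <- transform$R
  r2d <- 180 / pi
  add <- asin(max(-1, min(1, -R[2, 3])))
  flex <- atan2(R[1, 3], R[3, 3])
  int <- atan2(R[2, 1], R[2, 2])
  u <- as.numeric(crossprod(R, transform$t))
  joint_pose(flexion = flex * r2d, adduction = add * r2d, internal = int * r2d,
             ap = u[1], ml = u[2], dp = u[3])
}

#' Apply a rigid transform to one or more points
#'
#' @param transform A `rigid_transform`.
#' @param points Numeric 3-vector or n x 3 matrix (mm).
#' @return Transformed points, same shape as the input.
#' @export
transform_point <- function(transform, points) {
  if (is.null(dim(points))) {
    as.numeric(transform$R %*% points + transform$t)
  } else {
    sweep(points %*% t(transform$R), 2, transform$t, "+")
  }
}

#' @rdname pose_to_transform
#' @param transform A `rigid_transform` to invert.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% transform$t)),
            class = "rigid_transform")
}

#' @rdname pose_to_transform
#' @param a,b Transforms to compose (`a` applied after `b`).
#' @export
compose_transforms <- function(a, b) {
  structure(list(R = a$R %*% b$R, t = as.numeric(a$R %*% b$t + a$t)),
            class = "rigid_transform")
}

.identity_transform <- function() {
  structure(list(R = diag(3), t = c(0, 0, 0)), class = "rigid_transform")
}

#' Read or write a pose trajectory as CSV
#'
#' Columns: `flexion_deg, adduction_deg, internal_deg, ap_mm, ml_mm, dp_mm`.
#' Sign convention (right knee): anterior, medial, proximal and tibial
#' internal rotation positive; translations expressed in the tibial frame.
#'
#' @param poses A list of [joint_pose()] objects.
#' @param path Output file.
#' @return `write_pose_csv` returns `path` invisibly; `read_pose_csv` a list
#'   of poses.
#' @export
write_pose_csv <- function(poses, path) {
  df <- do.call(rbind, lapply(poses, function(p) {
    data.frame(flexion_deg = p$flexion, adduction_deg = p$adduction,
               internal_deg = p$internal, ap_mm = p$ap, ml_mm = p$ml,
               dp_mm = p$dp)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @export
read_pose_csv <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    joint_pose(df$flexion_deg[i], df$adduction_deg[i], df$internal_deg[i],
               df$ap_mm[i], df$ml_mm[i], df$dp_mm[i])
  })
}
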