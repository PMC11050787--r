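# Virtual ligament bundles and the quadratic-to-linear force law.
#
# Each bundle is a tension-only nonlinear elastic fiber acting on the
# straight line between an origin fixed in the femoral-component frame and
# an insertion fixed in the tibial-component frame. Wrapping around bone or
# implant is deliberately not modeled.

#' Nonlinear ligament force law (quadratic-to-linear)
#'
#' Wismans/Blankevoort fiber force as a function of engineering strain:
#' zero when slack, quadratic at low strain and linear beyond twice the
#' transition strain `linear_limit`, with a C1-continuous junction:
#' \deqn{f(\epsilon) = 0 \quad (\epsilon \le 0)}
#' \deqn{f(\epsilon) = k\,\epsilon^2/(4\epsilon_\ell) \quad (0 < \epsilon \le 2\epsilon_\ell)}
#' \deqn{f(\epsilon) = k\,(\epsilon - \epsilon_\ell) \quad (\epsilon > 2\epsilon_\ell)}
#' The transition to linear behavior occurs at strain \eqn{2\epsilon_\ell}
#' (6\% with the default `linear_limit = 0.03`).
#'
#' @param strain Engineering strain (dimensionless), any real value(s).
#' @param stiffness_k Stiffness k in N per unit strain (> 0).
#' @param linear_limit Transition parameter \eqn{\epsilon_\ell} (> 0);
#'   quadratic-to-linear transition at `2 * linear_limit`.
#' @return Force in N (vectorized over `strain`), always >= 0.
#' @export
#' @examples
#' force_from_strain(0.11, 3300, 0.03) # linear branch: 3300 * (0.11 - 0.03)
force_from_strain <- function(strain, stiffness_k, linear_limit = 0.03) {
  stopifnot(stiffness_k > 0, linear_limit > 0)
  f <- numeric(length(strain))
  quad <- strain > 0 & strain <= 2 * linear_limit
  lin <- strain > 2 * linear_limit
  f[quad] <- stiffness_k * strain[quad]^2 / (4 * linear_limit)
  f[lin] <- stiffness_k * (strain[lin] - linear_limit)
  f
}

#' Rest length from a reference configuration
#'
#' The rest (zero-strain) length L0 is derived from the insertion-point
#' distance at the reference configuration and the strain the fiber is
#' assigned there: `L0 = distance / (1 + reference_strain)`.
#'
#' @param origin_world,insertion_world Insertion points, 3-vectors in a
#'   common frame (mm).
#' @param reference_strain Strain at the reference configuration (> -1).
#' @return Rest length in mm.
#' @export
rest_length_from_reference <- function(origin_world, insertion_world,
                                       reference_strain) {
  stopifnot(reference_strain > -1)
  d <- sqrt(sum((origin_world - insertion_world)^2))
  if (d <= 0) stop("degenerate bundle: coincident insertion points")
  d / (1 + reference_strain)
}

#' Define a virtual ligament bundle
#'
#' @param name Unique bundle label (e.g. `"PCL_al"`).
#' @param origin 3-vector, mm, fixed in the femoral-component frame.
#' @param insertion 3-vector, mm, fixed in the tibial-component frame.
#' @param stiffness_k Stiffness in N per unit strain (> 0).
#' @param reference_strain Strain assigned at the reference configuration.
#' @param linear_limit Force-law transition parameter (default 0.03, i.e.
#'   quadratic-to-linear transition at 6\% strain).
#' @param stiffness_scale Multiplier in `[0, 1]` used for virtual resection
#'   (default 1).
#' @param rest_length Rest length in mm; usually left `NA` and set by
#'   [calibrate_apparatus()] at the reference configuration.
#' @return An object of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, origin, insertion, stiffness_k,
                            reference_strain, linear_limit = 0.03,
                            stiffness_scale = 1, rest_length = NA_real_) {
  stopifnot(length(origin) == 3, length(insertion) == 3,
            stiffness_k > 0, linear_limit > 0,
            stiffness_scale >= 0, stiffness_scale <= 1,
            reference_strain > -1)
  if (!is.na(rest_length) && rest_length <= 0) stop("rest_length must be > 0")
  structure(list(name = as.character(name), origin = as.numeric(origin),
                 insertion = as.numeric(insertion),
                 stiffness_k = stiffness_k,
                 reference_strain = reference_strain,
                 linear_limit = linear_limit,
                 stiffness_scale = stiffness_scale,
                 rest_length = rest_length),
            class = "ligament_bundle")
}

#' Collect bundles into a ligament apparatus
#'
#' @param bundles A list of [ligament_bundle()] objects with unique names.
#' @return An object of class `ligament_apparatus`.
#' @export
ligament_apparatus <- function(bundles) {
  stopifnot(is.list(bundles),
            all(vapply(bundles, inherits, TRUE, "ligament_bundle")))
  nm <- vapply(bundles, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("bundle names must be unique")
  structure(list(bundles = setNames(bundles, nm)), class = "ligament_apparatus")
}

#' @export
print.ligament_apparatus <- function(x, ...) {
  cat(sprintf("ligament_apparatus with %d bundle(s):\n", length(x$bundles)))
  for (b in x$bundles) {
    cat(sprintf("  %-8s k=%6.0f N/strain  eps_r=%+.3f  scale=%.2f  L0=%s mm\n",
                b$name, b$stiffness_k, b$reference_strain, b$stiffness_scale,
                if (is.na(b$rest_length)) "uncal." else sprintf("%.2f", b$rest_length)))
  }
  invisible(x)
}

#' Calibrate bundle rest lengths at a reference configuration
#'
#' Sets each bundle's rest length so that its strain at the given relative
#' pose equals its `reference_strain`.
#'
#' @param apparatus A [ligament_apparatus()].
#' @param transform `rigid_transform` of the tibial frame w.r.t. the femoral
#'   frame at the reference configuration.
#' @return The calibrated apparatus.
#' @export
calibrate_apparatus <- function(apparatus, transform) {
  apparatus$bundles <- lapply(apparatus$bundles, function(b) {
    ins_w <- transform_point(transform, b$insertion)
    b$rest_length <- rest_length_from_reference(b$origin, ins_w,
                                                b$reference_strain)
    b
  })
  apparatus
}

.bundle_strain <- function(bundle, transform) {
  if (is.na(bundle$rest_length)) stop("uncalibrated bundle: ", bundle$name)
  ins_w <- transform_point(transform, bundle$insertion)
  d <- sqrt(sum((bundle$origin - ins_w)^2))
  d / bundle$rest_length - 1
}

#' Force vector of a single bundle
#'
#' Tension-only force applied at the tibial insertion point, directed from
#' the insertion toward the femoral origin. Magnitude is
#' `stiffness_scale * force_from_strain(strain)`.
#'
#' @param bundle A calibrated [ligament_bundle()].
#' @param transform `rigid_transform` of the tibial frame w.r.t. the femoral
#'   frame.
#' @return List with `force` (3-vector, N, femoral frame, acting on the
#'   tibial component), `magnitude` (N), `strain`, and `insertion_world`
#'   (mm, femoral frame).
#' @export
bundle_force_vector <- function(bundle, transform) {
  if (is.na(bundle$rest_length)) stop("uncalibrated bundle: ", bundle$name)
  ins_w <- transform_point(transform, bundle$insertion)
  dvec <- bundle$origin - ins_w
  d <- sqrt(sum(dvec^2))
  strain <- d / bundle$rest_length - 1
  mag <- bundle$stiffness_scale *
    force_from_strain(strain, bundle$stiffness_k, bundle$linear_limit)
  force <- if (mag > 0 && d > 0) mag * dvec / d else c(0, 0, 0)
  list(force = force, magnitude = mag, strain = strain, insertion_world = ins_w)
}

#' Resultant wrench of the apparatus on the tibial component
#'
#' Sum of all bundle forces and their moments about a reference point,
#' expressed in the femoral frame.
#'
#' @param apparatus A calibrated [ligament_apparatus()].
#' @param transform `rigid_transform` of the tibial frame w.r.t. the femoral
#'   frame.
#' @param moment_reference_point 3-vector, mm, femoral frame (default origin).
#' @return List with `force` (N), `moment` (N mm), and `magnitudes` (named
#'   per-bundle scalar forces, N).
#' @export
apparatus_wrench <- function(apparatus, transform,
                             moment_reference_point = c(0, 0, 0)) {
  force <- c(0, 0, 0)
  moment <- c(0, 0, 0)
  mags <- numeric(length(apparatus$bundles))
  names(mags) <- names(apparatus$bundles)
  for (i in seq_along(apparatus$bundles)) {
    bf <- bundle_force_vector(apparatus$bundles[[i]], transform)
    force <- force + bf$force
    r <- bf$insertion_world - moment_reference_point
    moment <- moment + c(r[2] * bf$force[3] - r[3] * bf$force[2],
                         r[3] * bf$force[1] - r[1] * bf$force[3],
                         r[1] * bf$force[2] - r[2] * bf$force[1])
    mags[i] <- bf$magnitude
  }
  list(force = force, moment = moment, magnitudes = mags)
}

#' Virtual resection: scale the stiffness of matching bundles
#'
#' Sets `stiffness_scale` of every bundle whose name starts with
#' `bundle_name_prefix`. Errors if nothing matches, guarding against silent
#' no-op parameter sweeps.
#'
#' @param apparatus A [ligament_apparatus()].
#' @param bundle_name_prefix Name prefix, e.g. `"PCL"`.
#' @param scale New stiffness scale in `[0, 1]` (0 = fully resected).
#' @return The updated apparatus.
#' @export
set_resection <- function(apparatus, bundle_name_prefix, scale) {
  stopifnot(scale >= 0, scale <= 1)
  hit <- startsWith(names(apparatus$bundles), bundle_name_prefix)
  if (!any(hit)) stop("no bundle matches prefix '", bundle_name_prefix, "'")
  apparatus$bundles[hit] <- lapply(apparatus$bundles[hit], function(b) {
    b$stiffness_scale <- scale
    b
  })
  apparatus
}

#' Read or write a ligament set as YAML
#'
#' Fields per bundle: `name`, `origin` (mm, femoral frame), `insertion` (mm,
#' tibial frame), `stiffness_k` (N per unit strain), `reference_strain`,
#' `linear_limit`, `stiffness_scale`.
#'
#' @param apparatus A [ligament_apparatus()].
#' @param path File path.
#' @return `write_ligament_yaml` returns `path` invisibly;
#'   `read_ligament_yaml` an (uncalibrated) apparatus.
#' @export
write_ligament_yaml <- function(apparatus, path) {
  out <- lapply(unname(apparatus$bundles), function(b) {
    list(name = b$name, origin = b$origin, insertion = b$insertion,
         stiffness_k = b$stiffness_k, reference_strain = b$reference_strain,
         linear_limit = b$linear_limit, stiffness_scale = b$stiffness_scale)
  })
  yaml::write_yaml(list(bundles = out), path)
  invisible(path)
}

#' @rdname write_ligament_yaml
#' @export
read_ligament_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  ligament_apparatus(lapply(raw$bundles, function(b) {
    ligament_bundle(b$name, unlist(b$origin), unlist(b$insertion),
                    b$stiffness_k, b$reference_strain, b$linear_limit,
                    b$stiffness_scale)
  }))
}
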