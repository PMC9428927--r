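# The anatomical coordinate system (ACS) is a joint-centered orthonormal
# frame: X is abduction(+)/adduction(-), Y is flexion(+)/extension(-), Z is
# long-axis rotation (+ external). Rotations compose in the fixed "XYZ"
# order (X applied first): R = Rz(lar) %*% Ry(fe) %*% Rx(abad), about axes
# fixed in the proximal frame, pivoting at the joint center.

rot_x_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z_deg <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Composed joint rotation for a pose
#'
#' `R = Rz(lar) %*% Ry(fe) %*% Rx(abad)` (degrees): the "XYZ" rotation order
#' with X applied first.
#'
#' @param abad,fe,lar angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
pose_rotation <- function(abad, fe, lar) {
  rot_z_deg(lar) %*% rot_y_deg(fe) %*% rot_x_deg(abad)
}

#' A joint pose
#'
#' @param abad abduction(+)/adduction(-) angle about X, degrees.
#' @param fe flexion(+)/extension(-) angle about Y, degrees.
#' @param lar external(+)/internal(-) long-axis rotation about Z, degrees.
#' @param offset translational offset, mm, expressed in ACS axes.
#' @export
pose <- function(abad = 0, fe = 0, lar = 0, offset = c(0, 0, 0)) {
  stopifnot(all(is.finite(c(abad, fe, lar, offset))), length(offset) == 3)
  structure(list(abad = abad, fe = fe, lar = lar, offset = as.numeric(offset)),
            class = "pose")
}

#' Build the anatomical coordinate system for a ball-and-socket joint
#'
#' The origin is the superimposed fitted-sphere center. In the neutral pose
#' the distal long axis points toward the ground, so the ACS Z axis is the
#' ground normal. The X (abduction) axis is the component of
#' `reference_axis` perpendicular to Z; Y completes the right-handed frame
#' (`x cross y = z`).
#'
#' @param acetabulum,head `fitted_sphere` objects for socket and head. Their
#'   centers must coincide within `tol`, unless `rearticulation` (a
#'   [rigid_transform()] to be applied to the head/distal element) is given.
#' @param long_axis `fitted_cylinder` for the distal long axis (e.g. the
#'   femoral condyles); in neutral it must point within 80 degrees of the
#'   vertical, otherwise the neutral convention is unresolvable.
#' @param ground_normal unit vector perpendicular to the ground (+up).
#' @param reference_axis direction hint fixing the azimuth of the X axis.
#' @param tol sphere-center superimposition tolerance (mm).
#' @return an `acs`: `origin`, 3 x 3 `axes` (columns x, y, z),
#'   `rotation_order = "XYZ"`.
#' @export
build_acs <- function(acetabulum, head, long_axis,
                      ground_normal = c(0, 0, 1),
                      reference_axis = c(1, 0, 0),
                      rearticulation = NULL, tol = 1e-3) {
  head_center <- head$center
  if (!is.null(rearticulation))
    head_center <- as.vector(rearticulation$rotation %*% head_center) +
      rearticulation$translation
  if (sqrt(sum((head_center - acetabulum$center)^2)) > tol)
    stop("sphere centers not superimposed: rearticulate first ",
         "or pass the rearticulation transform")
  z <- ground_normal / sqrt(sum(ground_normal^2))
  ax <- long_axis$axis_direction
  if (abs(sum(ax * z)) < cos(80 * pi / 180))
    stop("distal long axis is nearly parallel to the ground: ",
         "neutral orientation unresolvable")
  x <- reference_axis - sum(reference_axis * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9)
    stop("reference_axis is parallel to the ground normal")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],  # y = z cross x
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  structure(list(origin = as.numeric(acetabulum$center),
                 axes = cbind(x = x, y = y, z = z),
                 rotation_order = "XYZ"),
            class = "acs")
}

is_acs <- function(x) inherits(x, "acs")

#' @export
print.acs <- function(x, ...) {
  cat(sprintf("<acs origin=(%.3f, %.3f, %.3f) order=%s>\n", x$origin[1],
              x$origin[2], x$origin[3], x$rotation_order))
  invisible(x)
}

#' Assemble a joint rig
#'
#' The proximal mesh is fixed; the distal mesh must already be in the
#' neutral position (all joint angles 0,0,0), e.g. after applying the
#' rearticulation transform. Watertightness of both meshes is recorded so
#' the collision test can include the containment (swallowing) check.
#'
#' @param proximal,distal [tri_mesh()] objects.
#' @param acs an [build_acs()] result.
#' @param neutral_transform the [rigid_transform()] that realised the
#'   neutral pose (recorded for provenance; identity if the meshes were
#'   articulated already).
#' @return a `joint_rig`.
#' @export
joint_rig <- function(proximal, distal, acs,
                      neutral_transform = rigid_transform()) {
  stopifnot(is_tri_mesh(proximal), is_tri_mesh(distal), is_acs(acs))
  structure(list(proximal = proximal, distal = distal, acs = acs,
                 neutral_transform = neutral_transform,
                 proximal_closed = is_watertight(proximal),
                 distal_closed = is_watertight(distal)),
            class = "joint_rig")
}

#' @export
print.joint_rig <- function(x, ...) {
  cat(sprintf("<joint_rig proximal='%s' (%d f) distal='%s' (%d f)>\n",
              x$proximal$name, nrow(x$proximal$faces), x$distal$name,
              nrow(x$distal$faces)))
  invisible(x)
}

#' Pose the distal element
#'
#' The distal mesh is translated by `pose$offset` (expressed in ACS axes)
#' and rotated by `R = Rz(lar) Ry(fe) Rx(abad)` about the ACS axes. The
#' pivot is the ACS origin for static (3/4-DOF) sampling; with
#' `pivot_at_offset = TRUE` (6-DOF sampling) the pivot moves with the
#' offset, i.e. rotation is about `origin + offset`.
#'
#' @param rig a [joint_rig()].
#' @param pose a [pose()].
#' @param pivot_at_offset rotate about the offset joint center.
#' @return the posed distal [tri_mesh()].
#' @export
apply_pose <- function(rig, pose, pivot_at_offset = FALSE) {
  stopifnot(inherits(rig, "joint_rig"), inherits(pose, "pose"))
  A <- rig$acs$axes
  M <- A %*% pose_rotation(pose$abad, pose$fe, pose$lar) %*% t(A)
  o <- rig$acs$origin
  t_world <- as.vector(A %*% pose$offset)
  v <- rig$distal$vertices
  if (pivot_at_offset) {
    v <- sweep(sweep(v, 2, o) %*% t(M), 2, o + t_world, "+")
  } else {
    v <- sweep(sweep(v, 2, o - t_world) %*% t(M), 2, o, "+")
  }
  out <- rig$distal
  out$vertices <- v
  out
}

#' Save / load a rig configuration
#'
#' Serialises the ACS (origin, axes, rotation order), the neutral transform
#' and the mesh names to JSON. Meshes themselves travel separately as
#' OBJ/PLY/STL.
#'
#' @param rig a [joint_rig()].
#' @param path JSON path.
#' @export
save_rig_config <- function(rig, path) {
  payload <- list(
    origin = rig$acs$origin,
    axes = as.vector(rig$acs$axes), # column-major x, y, z
    rotation_order = rig$acs$rotation_order,
    neutral_rotation = as.vector(rig$neutral_transform$rotation),
    neutral_translation = rig$neutral_transform$translation,
    proximal = rig$proximal$name,
    distal = rig$distal$name)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_rig_config
#' @param proximal,distal the meshes the configuration refers to.
#' @export
load_rig_config <- function(path, proximal, distal) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  acs <- structure(list(origin = as.numeric(cfg$origin),
                        axes = matrix(as.numeric(cfg$axes), 3, 3,
                                      dimnames = list(NULL, c("x", "y", "z"))),
                        rotation_order = cfg$rotation_order),
                   class = "acs")
  nt <- rigid_transform(matrix(as.numeric(cfg$neutral_rotation), 3, 3),
                        as.numeric(cfg$neutral_translation))
  joint_rig(proximal, distal, acs, nt)
}
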