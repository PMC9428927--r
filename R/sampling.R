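# Pose-grid generation and viability classification. A pose is viable when
# the two bone meshes do not interpenetrate. Regimes:
#   3dof - rotations only, tested at zero offset;
#   4dof - rotations plus one static translation (joint-spacing proxy);
#   6dof - rotations tested at every vertex of a small offset sphere; a pose
#          is viable when it clears at AT LEAST ONE vertex (union
#          semantics), with the rotation pivot moved to that vertex.

#' Euler-angle pose grid
#'
#' Defaults follow the hip-joint convention: flexion-extension and long-axis
#' rotation through -180..180 degrees, abduction-adduction through -90..90,
#' sampled at 5-degree intervals (197,173 poses).
#'
#' @param fe_range,abad_range,lar_range inclusive degree ranges, `c(min, max)`.
#' @param step grid step in degrees; each range must be divisible by it.
#' @return a `pose_grid`.
#' @export
pose_grid <- function(fe_range = c(-180, 180), abad_range = c(-90, 90),
                      lar_range = c(-180, 180), step = 5) {
  if (step <= 0) stop("step must be > 0")
  for (r in list(fe_range, abad_range, lar_range)) {
    if (length(r) != 2 || r[1] > r[2]) stop("ranges must be c(min, max)")
    if (abs((r[2] - r[1]) / step - round((r[2] - r[1]) / step)) > 1e-9)
      stop("range not divisible by step")
  }
  structure(list(fe_range = fe_range, abad_range = abad_range,
                 lar_range = lar_range, step = step),
            class = "pose_grid")
}

grid_axis_values <- function(grid) {
  list(abad = seq(grid$abad_range[1], grid$abad_range[2], by = grid$step),
       fe = seq(grid$fe_range[1], grid$fe_range[2], by = grid$step),
       lar = seq(grid$lar_range[1], grid$lar_range[2], by = grid$step))
}

#' Number of poses in a grid
#' @param grid a [pose_grid()].
#' @export
grid_size <- function(grid) {
  ax <- grid_axis_values(grid)
  length(ax$abad) * length(ax$fe) * length(ax$lar)
}

#' @export
print.pose_grid <- function(x, ...) {
  cat(sprintf(
    "<pose_grid fe %g..%g abad %g..%g lar %g..%g step %g: %d poses>\n",
    x$fe_range[1], x$fe_range[2], x$abad_range[1], x$abad_range[2],
    x$lar_range[1], x$lar_range[2], x$step, grid_size(x)))
  invisible(x)
}

#' Enumerate the poses of a grid
#'
#' Deterministic ordering: abad varies slowest, then fe, then lar.
#'
#' @param grid a [pose_grid()].
#' @return data.frame with columns `abad`, `fe`, `lar` (degrees).
#' @export
generate_grid <- function(grid) {
  ax <- grid_axis_values(grid)
  df <- expand.grid(lar = ax$lar, fe = ax$fe, abad = ax$abad,
                    KEEP.OUT.ATTRS = FALSE)
  df[, c("abad", "fe", "lar")]
}

#' Offset sphere for 6-DOF translational sampling
#'
#' A coarse UV sphere whose vertices are the translational offsets at which
#' rotational poses are sampled; its radius is the joint spacing (the
#' difference of the fitted radii). The default 8 axis divisions x 4 height
#' divisions give 32 faces and 26 vertices.
#'
#' @param radius sphere radius, mm.
#' @param axis_divisions azimuthal divisions (>= 3).
#' @param height_divisions polar divisions (>= 2).
#' @return an `offset_sphere`: `radius`, divisions, `vertices`
#'   (`axis_divisions * (height_divisions - 1) + 2` rows), `n_faces`
#'   (`axis_divisions * height_divisions`, counting cap triangles and
#'   inter-ring quads).
#' @export
build_offset_sphere <- function(radius, axis_divisions = 8,
                                height_divisions = 4) {
  if (radius <= 0) stop("offset sphere radius must be > 0")
  if (axis_divisions < 3 || height_divisions < 2)
    stop("need axis_divisions >= 3 and height_divisions >= 2")
  a <- as.integer(axis_divisions)
  h <- as.integer(height_divisions)
  theta <- pi * seq_len(h - 1) / h          # ring polar angles
  phi <- 2 * pi * (seq_len(a) - 1) / a      # azimuths
  rings <- do.call(rbind, lapply(theta, function(th)
    cbind(radius * sin(th) * cos(phi), radius * sin(th) * sin(phi),
          radius * cos(th))))
  vertices <- rbind(c(0, 0, radius), rings, c(0, 0, -radius))
  structure(list(radius = radius, axis_divisions = a, height_divisions = h,
                 vertices = vertices, n_faces = a * h),
            class = "offset_sphere")
}

#' @export
print.offset_sphere <- function(x, ...) {
  cat(sprintf("<offset_sphere r=%.3f mm, %d vertices, %d faces>\n", x$radius,
              nrow(x$vertices), x$n_faces))
  invisible(x)
}

#' Do two meshes interpenetrate?
#'
#' TRUE when any triangle of `a` intersects any triangle of `b`, or when one
#' watertight mesh lies entirely inside the other (ray-parity containment
#' test). Accelerated by an AABB bounding-volume hierarchy; the result is
#' identical to the brute-force all-pairs triangle test. Shared-boundary
#' contact with penetration shallower than `tol` counts as non-colliding.
#'
#' @param a,b [tri_mesh()] objects.
#' @param tol contact tolerance, mm (default 0: only true interpenetration).
#' @export
check_collision <- function(a, b, tol = 0) {
  stopifnot(is_tri_mesh(a), is_tri_mesh(b))
  cpp_check_collision(a$vertices, a$faces - 1L, b$vertices, b$faces - 1L,
                      tol, is_watertight(a), is_watertight(b))
}

#' Classify the viability of every grid pose
#'
#' Poses the distal element at every grid pose (and, for 4/6-DOF, every
#' translational offset) and discards poses with bone-mesh interpenetration.
#'
#' @param rig a [joint_rig()].
#' @param grid a [pose_grid()].
#' @param regime "3dof", "4dof" or "6dof".
#' @param static_offset 4-DOF only: the static translation (mm, ACS axes);
#'   either a 3-vector or a scalar spacing applied along `offset_direction`.
#' @param offset_sphere 6-DOF only: an [build_offset_sphere()] result.
#' @param offset_direction unit 3-vector (ACS axes) used when
#'   `static_offset` is scalar; default +Y, the single translation axis.
#' @param include_center 6-DOF: also test the sphere center (zero offset).
#' @param record_offsets 6-DOF: test every sphere vertex so the per-pose set
#'   of cleared offsets is complete; with `FALSE`, testing of a pose stops
#'   at its first cleared vertex (viability is unchanged -- it is a union --
#'   but untested vertices are NA in the clear matrix).
#' @param tol contact tolerance (mm) forwarded to the collision test.
#' @return a `rom_map`: the grid, regime, per-pose viability, and for 6-DOF
#'   the number (and identity) of offset-sphere vertices each pose cleared.
#' @export
classify_poses <- function(rig, grid, regime = c("3dof", "4dof", "6dof"),
                           static_offset = NULL, offset_sphere = NULL,
                           offset_direction = c(0, 1, 0),
                           include_center = FALSE, record_offsets = TRUE,
                           tol = 0) {
  stopifnot(inherits(rig, "joint_rig"), inherits(grid, "pose_grid"))
  regime <- match.arg(regime)
  offsets <- switch(regime,
    "3dof" = matrix(0, 1, 3),
    "4dof" = {
      if (is.null(static_offset)) stop("4dof requires static_offset")
      if (length(static_offset) == 1) {
        d <- offset_direction / sqrt(sum(offset_direction^2))
        matrix(static_offset * d, 1, 3)
      } else matrix(as.numeric(static_offset), 1, 3)
    },
    "6dof" = {
      if (is.null(offset_sphere)) stop("6dof requires offset_sphere")
      v <- offset_sphere$vertices
      if (include_center) v <- rbind(c(0, 0, 0), v)
      v
    })
  poses <- generate_grid(grid)
  A <- rig$acs$axes
  offsets_world <- offsets %*% t(A)
  clear <- cpp_classify_poses(
    rig$proximal$vertices, rig$proximal$faces - 1L,
    rig$distal$vertices, rig$distal$faces - 1L,
    as.matrix(poses), A, rig$acs$origin, offsets_world,
    pivot_at_offset = (regime == "6dof"), tol = tol,
    prox_closed = rig$proximal_closed, dist_closed = rig$distal_closed,
    early_exit = (regime == "6dof" && !record_offsets))
  n_clear <- rowSums(clear, na.rm = TRUE)
  structure(list(grid = grid, regime = regime, poses = poses,
                 viable = n_clear > 0L,
                 n_offsets_clear = as.integer(n_clear),
                 offsets = offsets,
                 clear_matrix = if (regime == "6dof") clear else NULL,
                 static_offset = if (regime == "4dof") offsets[1, ] else NULL,
                 offset_sphere = offset_sphere,
                 tol = tol),
            class = "rom_map")
}

#' @export
print.rom_map <- function(x, ...) {
  cat(sprintf("<rom_map %s: %d / %d poses viable>\n", x$regime,
              sum(x$viable), nrow(x$poses)))
  invisible(x)
}

#' Viable poses of a ROM map
#' @param map a `rom_map`.
#' @return data.frame of the viable `abad`, `fe`, `lar` triples.
#' @export
viable_poses <- function(map) {
  stopifnot(inherits(map, "rom_map"))
  map$poses[map$viable, , drop = FALSE]
}

#' Write / read a ROM map as CSV plus a JSON metadata sidecar
#'
#' The CSV has columns `abad_deg`, `fe_deg`, `lar_deg`, `viable` (0/1) and
#' `n_offsets_clear`; grid, regime and offset metadata go to `<path>.json`.
#'
#' @param map a `rom_map`.
#' @param path CSV output path.
#' @export
write_rom_map <- function(map, path) {
  df <- data.frame(abad_deg = map$poses$abad, fe_deg = map$poses$fe,
                   lar_deg = map$poses$lar,
                   viable = as.integer(map$viable),
                   n_offsets_clear = map$n_offsets_clear)
  write.csv(df, path, row.names = FALSE)
  meta <- list(regime = map$regime,
               fe_range = map$grid$fe_range,
               abad_range = map$grid$abad_range,
               lar_range = map$grid$lar_range,
               step = map$grid$step,
               static_offset = map$static_offset,
               offset_sphere_radius = map$offset_sphere$radius,
               tol = map$tol,
               package_version = as.character(utils::packageVersion("romap")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rom_map
#' @export
read_rom_map <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- pose_grid(fe_range = as.numeric(meta$fe_range),
                    abad_range = as.numeric(meta$abad_range),
                    lar_range = as.numeric(meta$lar_range),
                    step = as.numeric(meta$step))
  structure(list(grid = grid, regime = meta$regime,
                 poses = data.frame(abad = df$abad_deg, fe = df$fe_deg,
                                    lar = df$lar_deg),
                 viable = df$viable > 0,
                 n_offsets_clear = df$n_offsets_clear,
                 offsets = NULL, clear_matrix = NULL,
                 static_offset = meta$static_offset,
                 offset_sphere = NULL,
                 tol = meta$tol),
            class = "rom_map")
}
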