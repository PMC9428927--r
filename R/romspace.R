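# Cosine-corrected Euler shape space and alpha-shape volumes. Euler
# parameterisation distorts the pose-space metric near gimbal alignment of
# the two outer rotations of R = Rz %*% Ry %*% Rx: as the middle (fe) angle
# approaches +-90 degrees the first-applied (abad) coordinate degenerates,
# so the default correction scales abad by cos(fe). Volumes are reported in
# degree^3 of the corrected space.

#' Map viable poses into the cosine-corrected shape space
#'
#' @param map a `rom_map` (its viable poses are used) or a data.frame with
#'   `abad`, `fe`, `lar` columns (degrees).
#' @param correction which coordinate is scaled by the cosine of which
#'   angle; default `"abad_by_fe"` (from the XYZ composition order).
#'   `"none"` returns raw angles.
#' @return a `corrected_cloud`: `points` (n x 3, corrected degrees, columns
#'   abad/fe/lar), `correction`.
#' @export
cosine_correct <- function(map, correction = c("abad_by_fe", "lar_by_fe",
                                               "none")) {
  correction <- match.arg(correction)
  df <- if (inherits(map, "rom_map")) viable_poses(map) else as.data.frame(map)
  if (nrow(df) == 0) stop("no viable poses to map")
  pts <- cbind(abad = df$abad, fe = df$fe, lar = df$lar)
  cf <- cos(df$fe * pi / 180)
  pts <- switch(correction,
                abad_by_fe = cbind(abad = df$abad * cf, fe = df$fe,
                                   lar = df$lar),
                lar_by_fe = cbind(abad = df$abad, fe = df$fe,
                                  lar = df$lar * cf),
                none = pts)
  structure(list(points = pts, correction = correction),
            class = "corrected_cloud")
}

#' @export
print.corrected_cloud <- function(x, ...) {
  cat(sprintf("<corrected_cloud %d points, correction=%s>\n",
              nrow(x$points), x$correction))
  invisible(x)
}

#' Default alpha for a pose grid
#'
#' 1.5 x the grid step: small enough to preserve concavities and unviable
#' "islands", large enough to connect diagonally adjacent grid cells.
#'
#' @param grid a [pose_grid()] (or a numeric step).
#' @export
default_alpha <- function(grid) {
  step <- if (inherits(grid, "pose_grid")) grid$step else as.numeric(grid)
  1.5 * step
}

#' Alpha-shape volume of a pose cloud
#'
#' Builds the 3D alpha complex from the Delaunay triangulation (tetrahedra
#' with circumradius <= alpha are kept); the volume is the sum of kept
#' tetrahedra, in degree^3 of the corrected space. `alpha = Inf` gives the
#' convex hull.
#'
#' @param cloud a `corrected_cloud` (or an n x 3 matrix), n >= 4,
#'   non-coplanar.
#' @param alpha circumradius threshold in corrected degrees (> 0 or Inf).
#' @return an `alpha_shape_result`: `alpha`, `volume` (degree^3),
#'   `n_components`, plus `hull_volume` and tetrahedron counts.
#' @export
alpha_volume <- function(cloud, alpha) {
  pts <- if (inherits(cloud, "corrected_cloud")) cloud$points else
    as.matrix(cloud)
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0)
    stop("alpha must be a single value > 0 (Inf for the convex hull)")
  if (nrow(pts) < 4) stop("need at least 4 points")
  sv <- svd(sweep(pts, 2, colMeans(pts)))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("all points are coplanar: no 3D alpha shape")
  res <- cpp_alpha_complex(pts, alpha, seed = 1L)
  structure(list(alpha = alpha, volume = res$volume,
                 n_components = res$n_components,
                 hull_volume = res$hull_volume,
                 n_tetrahedra = res$n_tetrahedra, n_kept = res$n_kept),
            class = "alpha_shape_result")
}

#' @export
print.alpha_shape_result <- function(x, ...) {
  cat(sprintf(
    "<alpha_shape alpha=%g: volume %.0f deg^3 in %d component(s)>\n",
    x$alpha, x$volume, x$n_components))
  invisible(x)
}

#' Compare two ROM maps on the same grid
#'
#' @param a,b `rom_map` objects over identical grids.
#' @return a list: viable counts, `only_a`, `only_b`, `intersection`,
#'   `jaccard`, and per-axis marginal extents (min/max viable angle per axis
#'   per map).
#' @export
compare_maps <- function(a, b) {
  stopifnot(inherits(a, "rom_map"), inherits(b, "rom_map"))
  if (!identical(unclass(a$grid), unclass(b$grid)))
    stop("ROM maps are on different grids")
  va <- a$viable
  vb <- b$viable
  inter <- sum(va & vb)
  uni <- sum(va | vb)
  extents <- function(map) {
    vp <- viable_poses(map)
    if (nrow(vp) == 0)
      return(data.frame(axis = c("abad", "fe", "lar"), min = NA, max = NA))
    data.frame(axis = c("abad", "fe", "lar"),
               min = c(min(vp$abad), min(vp$fe), min(vp$lar)),
               max = c(max(vp$abad), max(vp$fe), max(vp$lar)))
  }
  list(n_a = sum(va), n_b = sum(vb),
       only_a = sum(va & !vb), only_b = sum(vb & !va),
       intersection = inter,
       jaccard = if (uni == 0) NA_real_ else inter / uni,
       extents_a = extents(a), extents_b = extents(b))
}

#' Ratio of two alpha-shape volumes, as a percentage
#'
#' @param a,b `alpha_shape_result` objects (or bare volumes); `b` is the
#'   reference (denominator).
#' @return `100 * a / b`, rounded to 2 decimals.
#' @export
volume_ratio <- function(a, b) {
  va <- if (inherits(a, "alpha_shape_result")) a$volume else as.numeric(a)
  vb <- if (inherits(b, "alpha_shape_result")) b$volume else as.numeric(b)
  if (any(vb <= 0)) stop("reference volume must be > 0")
  round(100 * va / vb, 2)
}

#' Export a corrected cloud as an ASCII PLY point cloud
#' @param cloud a `corrected_cloud`.
#' @param path output path.
#' @export
export_cloud_ply <- function(cloud, path) {
  pts <- cloud$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment correction=%s", cloud$correction),
               sprintf("element vertex %d", nrow(pts)),
               "property double x", "property double y", "property double z",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  invisible(path)
}
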