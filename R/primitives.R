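# Primitive shapes fitted to articular surfaces define joint centers and
# joint spacing. Sphere fitting is a Coope-style algebraic linear solve
# followed by Gauss-Newton orthogonal-distance refinement; cylinder fitting
# initialises the axis by PCA and refines axis + radius by
# Levenberg-Marquardt (minpack.lm).

#' Least-squares sphere fit
#'
#' Algebraic (linearised) fit followed by geometric (orthogonal-distance)
#' refinement. The RMS residual is the root mean square of
#' `| ||p_i - center|| - radius |`.
#'
#' @param points n x 3 matrix of surface points (mm), n >= 4, not coplanar.
#' @return a `fitted_sphere`: `center` (mm), `radius` (mm), `rms_residual`
#'   (mm).
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  if (nrow(points) < 4) stop("sphere fit needs at least 4 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("points are (near-)coplanar: sphere is not identifiable")
  # algebraic: ||p||^2 = 2 p . c + (r^2 - ||c||^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  # Gauss-Newton on (center, radius) with residual dist - r
  par <- c(center, radius)
  for (iter in 1:50) {
    d <- sweep(points, 2, par[1:3])
    dist <- sqrt(rowSums(d^2))
    r <- dist - par[4]
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -r), error = function(e) rep(0, 4))
    par <- par + step
    if (max(abs(step)) < 1e-12) break
  }
  d <- sweep(points, 2, par[1:3])
  res <- sqrt(rowSums(d^2)) - par[4]
  structure(list(center = unname(par[1:3]), radius = unname(par[4]),
                 rms_residual = sqrt(mean(res^2))),
            class = "fitted_sphere")
}

#' @export
print.fitted_sphere <- function(x, ...) {
  cat(sprintf("<fitted_sphere r=%.4f mm center=(%.3f, %.3f, %.3f) rms=%.2g>\n",
              x$radius, x$center[1], x$center[2], x$center[3], x$rms_residual))
  invisible(x)
}

#' Least-squares cylinder fit
#'
#' Axis initialised from the principal direction of the point cloud and
#' refined together with the radius by Levenberg-Marquardt on the orthogonal
#' distances. The axis direction is canonicalised to a positive Z component
#' (then positive X, then positive Y on ties): a cylinder axis is a line, so
#' `d` and `-d` are equivalent.
#'
#' @param points n x 3 matrix (mm), n >= 6, not collinear.
#' @return a `fitted_cylinder`: `axis_point` (the centroid projected onto the
#'   axis, mm), `axis_direction` (unit), `radius` (mm), `length` (extent of
#'   point projections, mm), `rms_residual` (mm).
#' @export
fit_cylinder <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  if (nrow(points) < 6) stop("cylinder fit needs at least 6 points")
  ctr <- colMeans(points)
  cen <- sweep(points, 2, ctr)
  sv <- svd(cen)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are (near-)collinear: cylinder is not identifiable")
  axis0 <- sv$v[, 1]

  sph2cart <- function(theta, phi)
    c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  theta0 <- acos(max(-1, min(1, axis0[3])))
  phi0 <- atan2(axis0[2], axis0[1])

  # residual: orthogonal distance to the axis minus the radius; the axis
  # passes through ctr + (u1*b1 + u2*b2) where (b1,b2) span the normal plane
  resid_fun <- function(p) {
    d <- sph2cart(p[1], p[2])
    b1 <- if (abs(d[3]) < 0.9) c(-d[2], d[1], 0) else c(0, -d[3], d[2])
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(d[2] * b1[3] - d[3] * b1[2],
            d[3] * b1[1] - d[1] * b1[3],
            d[1] * b1[2] - d[2] * b1[1])
    pt <- ctr + p[3] * b1 + p[4] * b2
    rel <- sweep(points, 2, pt)
    proj <- rel %*% d
    dist <- sqrt(pmax(rowSums(rel^2) - proj^2, 0))
    dist - p[5]
  }
  rel0 <- cen
  d0 <- sqrt(pmax(rowSums(rel0^2) - (rel0 %*% axis0)^2, 0))
  p0 <- c(theta0, phi0, 0, 0, mean(d0))
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  d <- sph2cart(p[1], p[2])
  # canonical sign
  flip <- if (abs(d[3]) > 1e-9) d[3] < 0 else if (abs(d[1]) > 1e-9) d[1] < 0 else d[2] < 0
  if (flip) d <- -d
  b1 <- if (abs(d[3]) < 0.9) c(-d[2], d[1], 0) else c(0, -d[3], d[2])
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(d[2] * b1[3] - d[3] * b1[2],
          d[3] * b1[1] - d[1] * b1[3],
          d[1] * b1[2] - d[2] * b1[1])
  pt <- ctr + p[3] * b1 + p[4] * b2
  rel <- sweep(points, 2, pt)
  proj <- as.vector(rel %*% d)
  axis_point <- pt + mean(proj) * d
  res <- sqrt(pmax(rowSums(rel^2) - proj^2, 0)) - p[5]
  structure(list(axis_point = unname(axis_point),
                 axis_direction = unname(d),
                 radius = unname(abs(p[5])),
                 length = diff(range(proj)),
                 rms_residual = sqrt(mean(res^2))),
            class = "fitted_cylinder")
}

#' @export
print.fitted_cylinder <- function(x, ...) {
  cat(sprintf(
    "<fitted_cylinder r=%.4f mm len=%.2f axis=(%.3f, %.3f, %.3f) rms=%.2g>\n",
    x$radius, x$length, x$axis_direction[1], x$axis_direction[2],
    x$axis_direction[3], x$rms_residual))
  invisible(x)
}

#' Rearticulation transform from fitted spheres
#'
#' Superimposes the centroids of the primitives fitted to the two articular
#' surfaces: a pure translation mapping the moving sphere's center onto the
#' fixed sphere's center. Orientation is left to the ACS step.
#'
#' @param moving_sphere,fixed_sphere `fitted_sphere` objects.
#' @return a [rigid_transform()] (identity rotation).
#' @export
rearticulate <- function(moving_sphere, fixed_sphere) {
  rigid_transform(diag(3), fixed_sphere$center - moving_sphere$center)
}

#' Joint spacing from the difference of fitted radii
#'
#' For a disarticulated ball-and-socket joint the difference between the
#' socket and head fitted radii approximates the joint spacing (a proxy for
#' the maximum articular-cartilage thickness).
#'
#' @param acetabulum,head `fitted_sphere` objects; the socket radius must not
#'   be smaller than the head radius.
#' @return a `joint_spacing`: `value` (mm), `source = "radii_difference"`.
#' @export
joint_spacing_from_radii <- function(acetabulum, head) {
  if (head$radius > acetabulum$radius + 1e-9)
    stop("femoral head radius exceeds acetabulum radius: non-physical articulation")
  joint_spacing(max(acetabulum$radius - head$radius, 0), "radii_difference")
}

#' Joint spacing value
#' @param value spacing in mm (>= 0).
#' @param source "radii_difference" or "configured".
#' @export
joint_spacing <- function(value, source = c("configured", "radii_difference")) {
  source <- match.arg(source)
  value <- as.numeric(value)
  if (value < 0) stop("joint spacing must be >= 0")
  structure(list(value = value, source = source), class = "joint_spacing")
}

#' Write fitted shapes to a JSON report
#' @param shapes named list of `fitted_sphere` / `fitted_cylinder` objects.
#' @param path output path.
#' @export
write_fit_report <- function(shapes, path) {
  payload <- lapply(shapes, function(s) {
    out <- unclass(s)
    out$type <- class(s)[1]
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
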