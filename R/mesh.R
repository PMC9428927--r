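# TriMesh: the substrate of every collision test. Vertices are stored as an
# n x 3 matrix in millimetres; faces as an m x 3 integer matrix of 1-based
# vertex indices. Degenerate (zero-area) faces are dropped at construction.

#' Construct a triangle mesh
#'
#' @param vertices numeric matrix (n x 3), coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based vertex indices.
#' @param name label carried through reports.
#' @param drop_degenerate drop zero-area faces (area < `area_tol`) with a
#'   warning instead of failing.
#' @param area_tol triangle area below which a face counts as degenerate
#'   (mm^2).
#' @return an object of class `tri_mesh` with elements `vertices`, `faces`,
#'   `name`.
#' @export
tri_mesh <- function(vertices, faces, name = "mesh", drop_degenerate = TRUE,
                     area_tol = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) < 1L) stop("mesh must have at least one face")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  areas <- triangle_areas(vertices, faces)
  if (any(areas <= area_tol)) {
    if (!drop_degenerate) stop("mesh contains degenerate (zero-area) faces")
    warning(sprintf("dropping %d degenerate face(s)", sum(areas <= area_tol)))
    faces <- faces[areas > area_tol, , drop = FALSE]
    if (nrow(faces) < 1L) stop("all faces degenerate")
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "tri_mesh")
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh '%s': %d vertices, %d faces>\n", x$name,
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

undirected_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Check mesh topology and geometry
#'
#' Reports watertightness (every edge shared by exactly two faces), the Euler
#' characteristic, degenerate-face count and (optionally) the number of
#' intersecting non-adjacent triangle pairs. Reporting only: the input is not
#' modified.
#'
#' @param mesh a [tri_mesh()].
#' @param self_intersections also count self-intersections (all-pairs test;
#'   quadratic in face count, intended for meshes up to a few thousand
#'   faces).
#' @return a list with `watertight`, `n_boundary_edges`, `n_nonmanifold_edges`,
#'   `euler_characteristic`, `n_degenerate`, and `self_intersections` (NA
#'   unless requested).
#' @export
validate_mesh <- function(mesh, self_intersections = FALSE) {
  stopifnot(is_tri_mesh(mesh))
  e <- undirected_edges(mesh$faces)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  n_boundary <- sum(cnt == 1L)
  n_nonmanifold <- sum(cnt > 2L)
  n_edges <- length(cnt)
  used <- sort(unique(as.vector(mesh$faces)))
  chi <- length(used) - n_edges + nrow(mesh$faces)
  si <- NA_integer_
  if (self_intersections) {
    si <- cpp_self_intersections(mesh$vertices, mesh$faces - 1L, 0)
  }
  list(watertight = (n_boundary == 0L && n_nonmanifold == 0L),
       n_boundary_edges = as.integer(n_boundary),
       n_nonmanifold_edges = as.integer(n_nonmanifold),
       euler_characteristic = as.integer(chi),
       n_degenerate = 0L, # degenerate faces are removed at construction
       self_intersections = si)
}

is_watertight <- function(mesh) validate_mesh(mesh)$watertight

#' Rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1 within 1e-8).
#' @param translation length-3 vector (mm).
#' @return a `rigid_transform` (list with `rotation`, `translation`).
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3)) || length(translation) != 3)
    stop("need a 3x3 rotation and length-3 translation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation part is not a proper rotation (orthonormal, det +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to a mesh
#'
#' Maps every vertex by `v' = R v + t`; faces are unchanged.
#'
#' @param mesh a [tri_mesh()].
#' @param transform a [rigid_transform()]; alternatively pass `rotation` and
#'   `translation` directly.
#' @param rotation,translation used when `transform` is missing.
#' @return the transformed [tri_mesh()].
#' @export
transform_mesh <- function(mesh, transform = NULL, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  stopifnot(is_tri_mesh(mesh))
  if (is.null(transform)) transform <- rigid_transform(rotation, translation)
  if (!inherits(transform, "rigid_transform"))
    transform <- rigid_transform(transform$rotation, transform$translation)
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2, transform$translation, "+")
  out <- mesh
  out$vertices <- v
  out
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  R <- t(transform$rotation)
  rigid_transform(R, -as.vector(R %*% transform$translation))
}

#' Vertex-selection mask
#'
#' Identifies the articular-surface vertices used for primitive fitting.
#' Indices are held 1-based in R; the on-disk format is one 0-based integer
#' per line.
#'
#' @param mesh_name name of the mesh the mask refers to.
#' @param indices integer vertex indices (1-based).
#' @export
vertex_mask <- function(mesh_name, indices) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0L) stop("empty vertex mask")
  if (min(indices) < 1L) stop("mask indices must be >= 1")
  structure(list(mesh_name = as.character(mesh_name), indices = indices),
            class = "vertex_mask")
}

#' Extract the points selected by a mask
#' @param mesh a [tri_mesh()].
#' @param mask a [vertex_mask()].
#' @return matrix of selected vertex coordinates.
#' @export
mask_points <- function(mesh, mask) {
  stopifnot(is_tri_mesh(mesh), inherits(mask, "vertex_mask"))
  if (max(mask$indices) > nrow(mesh$vertices))
    stop("mask indices exceed vertex count of mesh '", mesh$name, "'")
  mesh$vertices[mask$indices, , drop = FALSE]
}
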