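# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# unit tetrahedron at an offset
tetra_mesh <- function(offset = c(0, 0, 0), scale = 1, name = "tetra") {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) * scale
  v <- sweep(v, 2, offset, "+")
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  tri_mesh(v, f, name = name)
}

# icosphere-free UV sphere mesh (closed) for fitting/collision fixtures
uv_sphere_mesh <- function(center = c(0, 0, 0), radius = 1, n_theta = 12,
                           n_phi = 18, name = "sphere") {
  th <- seq(0, pi, length.out = n_theta)
  prof <- cbind(radius * sin(th), radius * cos(th))
  prof[1, 1] <- 0
  prof[n_theta, 1] <- 0
  seg <- rep(1L, nrow(prof))
  out <- romap:::revolve_profile(prof, seg, n_phi, name)
  m <- out$mesh
  m$vertices <- sweep(m$vertices, 2, center, "+")
  m
}

random_rotation <- function() {
  # QR of a random normal matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# --- independent collision oracle ------------------------------------------
# Segment-triangle crossing test (Moller-Trumbore, strict interior): two
# triangles intersect iff an edge of one strictly crosses the other. This is
# a different formulation from the package's interval-overlap test.

seg_tri_crosses <- function(p0, p1, a, b, c) {
  d <- p1 - p0
  e1 <- b - a
  e2 <- c - a
  pv <- c(d[2] * e2[3] - d[3] * e2[2],
          d[3] * e2[1] - d[1] * e2[3],
          d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * pv)
  if (abs(det) < 1e-14) return(FALSE)
  tv <- p0 - a
  u <- sum(tv * pv) / det
  if (u <= 0 || u >= 1) return(FALSE)
  qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
          tv[3] * e1[1] - tv[1] * e1[3],
          tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(d * qv) / det
  if (v <= 0 || u + v >= 1) return(FALSE)
  t <- sum(e2 * qv) / det
  t > 0 && t < 1
}

tri_tri_crosses_R <- function(t1, t2) {
  edges <- list(c(1, 2), c(2, 3), c(3, 1))
  for (e in edges) {
    if (seg_tri_crosses(t1[e[1], ], t1[e[2], ], t2[1, ], t2[2, ], t2[3, ]))
      return(TRUE)
    if (seg_tri_crosses(t2[e[1], ], t2[e[2], ], t1[1, ], t1[2, ], t1[3, ]))
      return(TRUE)
  }
  FALSE
}

collision_oracle_R <- function(ma, mb) {
  fa <- ma$faces
  fb <- mb$faces
  for (i in seq_len(nrow(fa))) {
    t1 <- ma$vertices[fa[i, ], , drop = FALSE]
    for (j in seq_len(nrow(fb))) {
      t2 <- mb$vertices[fb[j, ], , drop = FALSE]
      if (tri_tri_crosses_R(t1, t2)) return(TRUE)
    }
  }
  FALSE
}

# --- independent pose oracle ------------------------------------------------
# Homogeneous 4x4 matrices: translate to pivot, rotate about ACS axes,
# translate back; offset applied before rotation.

pose_oracle_vertices <- function(rig, p, pivot_at_offset = FALSE) {
  deg <- pi / 180
  Rx <- function(a) rbind(c(1, 0, 0), c(0, cos(a), -sin(a)),
                          c(0, sin(a), cos(a)))
  Ry <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                          c(-sin(a), 0, cos(a)))
  Rz <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                          c(0, 0, 1))
  hom_t <- function(t) { m <- diag(4); m[1:3, 4] <- t; m }
  hom_r <- function(R) { m <- diag(4); m[1:3, 1:3] <- R; m }
  A <- rig$acs$axes
  o <- rig$acs$origin
  R <- Rz(p$lar * deg) %*% Ry(p$fe * deg) %*% Rx(p$abad * deg)
  tw <- as.vector(A %*% p$offset)
  pivot <- if (pivot_at_offset) o + tw else o
  M <- hom_t(pivot) %*% hom_r(A %*% R %*% t(A)) %*% hom_t(-pivot) %*% hom_t(tw)
  v <- cbind(rig$distal$vertices, 1) %*% t(M)
  v[, 1:3]
}

# --- small synthetic joint rigs (built once per test file) ------------------

local_joint_cache <- new.env(parent = emptyenv())

cached_joint <- function(key, builder) {
  if (is.null(local_joint_cache[[key]]))
    local_joint_cache[[key]] <- builder()
  local_joint_cache[[key]]
}

ideal_joint_rig <- function(resolution = 1500) {
  cached_joint(paste0("ideal", resolution), function() {
    spec <- synthetic_joint_spec(mesh_resolution = resolution)
    j <- make_socket_joint(spec)
    head <- fit_sphere(mask_points(j$distal, j$head_mask))
    cup <- fit_sphere(mask_points(j$proximal, j$cup_mask))
    v <- j$distal$vertices
    cyl <- fit_cylinder(v[v[, 3] < -80 & v[, 3] > -200, ])
    acs <- build_acs(cup, head, cyl)
    list(joint = j, rig = joint_rig(j$proximal, j$distal, acs),
         head = head, cup = cup, spec = spec)
  })
}

# a noisy, tight joint that interpenetrates in the concentric neutral pose
# and frees up when translated out of the cup (-Z)
tight_noisy_joint_rig <- function(resolution = 1200) {
  cached_joint(paste0("tight", resolution), function() {
    spec <- synthetic_joint_spec(cup_radius = 17.652, head_radius = 17.552,
                                 cup_coverage = 70,
                                 mesh_resolution = resolution,
                                 noise_sd = 0.1, seed = 3)
    j <- make_socket_joint(spec)
    acs <- structure(list(origin = c(0, 0, 0),
                          axes = structure(diag(3),
                                           dimnames = list(NULL,
                                                           c("x", "y", "z"))),
                          rotation_order = "XYZ"), class = "acs")
    list(joint = j, rig = joint_rig(j$proximal, j$distal, acs), spec = spec)
  })
}
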