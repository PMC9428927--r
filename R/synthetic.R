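# Parametric ball-and-socket joint meshes with known ground truth. The
# distal ("femur-like") element is a closed surface of revolution: head
# sphere, cylindrical neck, conical flare, shaft, bottom cap, long axis
# along -Z in neutral. The proximal element is a spherical cup: cavity of
# radius cup_radius truncated at the rim polar angle cup_coverage (measured
# from the cavity pole, +Z), thickened into a closed shell. In the neutral,
# overlaid-centroid configuration the two sphere centers coincide at the
# origin, so the uniform clearance equals cup_radius - head_radius.
#
# For the ideal geometry the viability boundary under a pure tilt is the
# clearance cone: collision occurs when the rim circle (radius cup_radius,
# polar angle cup_coverage) comes within neck_radius of the neck axis,
#   tilt* = 180 - cup_coverage - asin(neck_radius / cup_radius)   [degrees]
# which the sampling modules can be checked against.

#' Specification of a synthetic ball-and-socket joint
#'
#' Defaults mimic a small hominin hip: head radius 17.552 mm, cup radius
#' 20 mm (joint spacing 2.448 mm), femoral length 289 mm.
#'
#' @param head_radius femoral-head sphere radius, mm.
#' @param cup_radius acetabular cavity radius, mm (>= head_radius).
#' @param cup_coverage polar angle of the cup rim from the cavity pole,
#'   degrees (0-180 exclusive); > 90 wraps past the equator.
#' @param neck_length,neck_radius femoral neck cylinder, mm.
#' @param shaft_length,shaft_radius femoral shaft cylinder, mm;
#'   `shaft_length = NULL` chooses it so the total femoral length is 289 mm.
#' @param shell_thickness cup shell thickness, mm.
#' @param mesh_resolution target vertex count per element.
#' @param noise_sd Gaussian surface noise along vertex normals, mm
#'   (emulates the irregularity of real subchondral bone).
#' @param seed RNG seed for the noise.
#' @export
synthetic_joint_spec <- function(head_radius = 17.552, cup_radius = 20.0,
                                 cup_coverage = 120, neck_length = 40,
                                 neck_radius = 6, shaft_length = NULL,
                                 shaft_radius = 9, shell_thickness = 2,
                                 mesh_resolution = 2000, noise_sd = 0,
                                 seed = 1) {
  if (cup_radius < head_radius)
    stop("cup_radius must be >= head_radius")
  if (cup_coverage <= 0 || cup_coverage >= 180)
    stop("cup_coverage must lie strictly between 0 and 180 degrees")
  if (neck_radius >= head_radius)
    stop("neck_radius must be smaller than head_radius")
  if (min(head_radius, neck_length, neck_radius, shaft_radius,
          shell_thickness) <= 0)
    stop("all lengths must be > 0")
  if (is.null(shaft_length)) {
    used <- head_radius + sqrt(head_radius^2 - neck_radius^2) + neck_length +
      max(shaft_radius - neck_radius, 0)
    shaft_length <- max(289 - used, 10)
  }
  structure(list(head_radius = head_radius, cup_radius = cup_radius,
                 cup_coverage = cup_coverage, neck_length = neck_length,
                 neck_radius = neck_radius, shaft_length = shaft_length,
                 shaft_radius = shaft_radius,
                 shell_thickness = shell_thickness,
                 mesh_resolution = mesh_resolution, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_joint_spec")
}

# closed surface of revolution about Z. profile: matrix of (radial, z) from
# pole (r=0) to pole (r=0); segment: integer label per profile row, so
# vertex masks for individual surfaces can be recovered.
revolve_profile <- function(profile, segment, m, name) {
  r <- profile[, 1]
  z <- profile[, 2]
  n <- length(r)
  if (r[1] != 0 || r[n] != 0) stop("profile must start and end on the axis")
  if (any(r[2:(n - 1)] <= 0)) stop("interior profile radii must be > 0")
  phi <- 2 * pi * (seq_len(m) - 1) / m
  verts <- matrix(0, 2 + (n - 2) * m, 3)
  vseg <- integer(nrow(verts))
  verts[1, ] <- c(0, 0, z[1])
  vseg[1] <- segment[1]
  for (i in 2:(n - 1)) {
    rows <- 1 + (i - 2) * m + seq_len(m)
    verts[rows, ] <- cbind(r[i] * cos(phi), r[i] * sin(phi), z[i])
    vseg[rows] <- segment[i]
  }
  nb <- nrow(verts)
  verts[nb, ] <- c(0, 0, z[n])
  vseg[nb] <- segment[n]
  ring <- function(i) 1 + (i - 2) * m + seq_len(m) # vertex ids of ring i
  faces <- list()
  r2 <- ring(2)
  faces[[1]] <- cbind(1, r2, c(r2[-1], r2[1]))
  if (n > 3) {
    for (i in 2:(n - 2)) {
      a <- ring(i)
      b <- ring(i + 1)
      a2 <- c(a[-1], a[1])
      b2 <- c(b[-1], b[1])
      faces[[length(faces) + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
  }
  rl <- ring(n - 1)
  faces[[length(faces) + 1]] <- cbind(nb, c(rl[-1], rl[1]), rl)
  mesh <- tri_mesh(verts, do.call(rbind, faces), name = name)
  list(mesh = mesh, vertex_segment = vseg)
}

# arc-length proportional sampling of a piecewise profile
sample_arc <- function(fr, to, npt) {
  # polar angles in degrees -> (r, z) rows on a sphere handled by caller
  seq(fr, to, length.out = max(npt, 2))
}

add_surface_noise <- function(mesh, sd, seed) {
  if (sd <= 0) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # area-weighted vertex normals
  a <- v[f[, 1], ]; b <- v[f[, 2], ]; c <- v[f[, 3], ]
  u <- b - a; w <- c - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      s <- rowsum(fn[, d], f[, k])
      vn[as.integer(rownames(s)), d] <- vn[as.integer(rownames(s)), d] + s
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  disp <- rnorm(nrow(v), 0, sd)
  out <- mesh
  out$vertices <- v + vn * disp
  out
}

#' Generate a synthetic ball-and-socket joint
#'
#' Builds the proximal (cup shell) and distal (head + neck + shaft) meshes
#' in the neutral, overlaid-centroid configuration, together with a ground
#' truth record and the articular-surface vertex masks used for fitting.
#'
#' @param spec a [synthetic_joint_spec()].
#' @return a list: `proximal`, `distal` ([tri_mesh()]), `head_mask`,
#'   `cup_mask` ([vertex_mask()] of the articular surfaces), and `truth`
#'   (true centers, radii, spacing, femoral length, the analytic clearance
#'   cone half-angle in degrees, and the spec).
#' @export
make_socket_joint <- function(spec) {
  stopifnot(inherits(spec, "synthetic_joint_spec"))
  hr <- spec$head_radius
  cr <- spec$cup_radius
  nr <- spec$neck_radius
  sr <- spec$shaft_radius
  th <- spec$shell_thickness
  cov <- spec$cup_coverage * pi / 180

  m <- max(16L, round(sqrt(spec$mesh_resolution)))
  nrows <- max(12L, ceiling(spec$mesh_resolution / m))

  # ---- distal: head arc + neck + flare + shaft + cap --------------------
  theta_n <- pi - asin(nr / hr) # junction polar angle of neck on head
  zn <- hr * cos(theta_n)
  z_neck <- zn - spec$neck_length
  flare <- max(sr - nr, 0.5)
  z_flare <- z_neck - flare
  z_end <- z_flare - spec$shaft_length
  seg_len <- c(hr * theta_n, spec$neck_length, flare * sqrt(2),
               spec$shaft_length, sr)
  npt <- pmax(3L, round(nrows * seg_len / sum(seg_len)))
  th_arc <- seq(0, theta_n, length.out = npt[1])
  prof <- rbind(
    cbind(hr * sin(th_arc), hr * cos(th_arc)),                       # head
    cbind(nr, seq(zn, z_neck, length.out = npt[2])[-1]),             # neck
    cbind(seq(nr, sr, length.out = npt[3])[-1],
          seq(z_neck, z_flare, length.out = npt[3])[-1]),            # flare
    cbind(sr, seq(z_flare, z_end, length.out = npt[4])[-1]),         # shaft
    cbind(seq(sr, 0, length.out = npt[5])[-1], z_end))               # cap
  seg <- rep(1:5, times = c(npt[1], npt[2] - 1, npt[3] - 1, npt[4] - 1,
                            npt[5] - 1))
  dist <- revolve_profile(prof, seg, m, "synthetic_femur")
  distal <- add_surface_noise(dist$mesh, spec$noise_sd, spec$seed)
  # articular = head-sphere vertices away from the neck junction
  head_rows <- which(dist$vertex_segment == 1)
  on_sphere <- abs(sqrt(rowSums(dist$mesh$vertices[head_rows, , drop = FALSE]^2)) -
                     hr) < 1e-6
  polar <- acos(pmin(1, pmax(-1,
    dist$mesh$vertices[head_rows, 3] / hr)))
  head_mask <- vertex_mask("synthetic_femur",
                           head_rows[on_sphere & polar < theta_n - 0.15])

  # ---- proximal: cavity arc + rim + outer arc ---------------------------
  seg_len_c <- c(cr * cov, th, (cr + th) * cov)
  nptc <- pmax(4L, round(nrows * seg_len_c / sum(seg_len_c)))
  th_in <- seq(0, cov, length.out = nptc[1])
  th_out <- seq(cov, 0, length.out = nptc[3])
  prof_c <- rbind(
    cbind(cr * sin(th_in), cr * cos(th_in)),                         # cavity
    cbind(seq(cr, cr + th, length.out = nptc[2])[-1] * sin(cov),
          seq(cr, cr + th, length.out = nptc[2])[-1] * cos(cov)),    # rim
    cbind((cr + th) * sin(th_out)[-1], (cr + th) * cos(th_out)[-1])) # outer
  seg_c <- rep(1:3, times = c(nptc[1], nptc[2] - 1, nptc[3] - 1))
  prox <- revolve_profile(prof_c, seg_c, m, "synthetic_cup")
  proximal <- add_surface_noise(prox$mesh, spec$noise_sd, spec$seed + 1)
  cup_rows <- which(prox$vertex_segment == 1)
  polar_c <- acos(pmin(1, pmax(-1, prox$mesh$vertices[cup_rows, 3] / cr)))
  cup_mask <- vertex_mask("synthetic_cup",
                          cup_rows[polar_c < cov - 0.1])

  clearance_deg <- 180 - spec$cup_coverage - asin(nr / cr) * 180 / pi
  truth <- list(center = c(0, 0, 0),
                head_radius = hr, cup_radius = cr,
                joint_spacing = cr - hr,
                femur_length = hr + abs(z_end),
                clearance_cone_deg = clearance_deg,
                long_axis = c(0, 0, -1),
                spec = spec)
  list(proximal = proximal, distal = distal,
       head_mask = head_mask, cup_mask = cup_mask, truth = truth)
}

#' Axis-aligned box mesh (12 triangles)
#'
#' A convenience fixture, e.g. a far, non-interacting plate standing in for
#' the rest of the pelvis.
#'
#' @param center box center (mm).
#' @param size edge lengths (scalar or length-3), mm.
#' @param name mesh label.
#' @export
box_mesh <- function(center = c(0, 0, 0), size = 10, name = "box") {
  size <- rep(size, length.out = 3)
  h <- size / 2
  v <- as.matrix(expand.grid(c(-h[1], h[1]), c(-h[2], h[2]),
                             c(-h[3], h[3])))
  v <- sweep(v, 2, center, "+")
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  tri_mesh(v, f, name = name)
}

#' Generate a gait-like joint-angle trace
#'
#' Smooth per-axis sinusoids with phase offsets plus Gaussian jitter;
#' deterministic under a fixed seed.
#'
#' @param amplitudes named degrees, `c(fe = , abad = , lar = )`.
#' @param n_frames number of frames (>= 2) over one gait cycle.
#' @param seed RNG seed.
#' @param jitter_sd Gaussian jitter SD, degrees.
#' @param cycle_s cycle duration, seconds.
#' @param condition label.
#' @return a [joint_angle_trace()].
#' @export
make_gait_trace <- function(amplitudes = c(fe = 40, abad = 10, lar = 10),
                            n_frames = 101, seed = 1, jitter_sd = 0.5,
                            cycle_s = 1, condition = "synthetic_gait") {
  if (n_frames < 2) stop("need at least 2 frames")
  amp <- c(fe = 0, abad = 0, lar = 0)
  amp[names(amplitudes)] <- amplitudes
  t <- seq(0, cycle_s, length.out = n_frames)
  ph <- t / cycle_s * 2 * pi
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  jitter <- function() if (jitter_sd > 0) rnorm(n_frames, 0, jitter_sd) else 0
  joint_angle_trace(data.frame(
    time = t,
    fe = amp["fe"] * sin(ph) + jitter(),
    abad = amp["abad"] * sin(ph + pi / 3) + jitter(),
    lar = amp["lar"] * sin(ph + 2 * pi / 3) + jitter()),
    condition = condition)
}
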