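# ACS construction and pose application.

make_sphere_fit <- function(center, radius = 1) {
  structure(list(center = center, radius = radius, rms_residual = 0),
            class = "fitted_sphere")
}
make_cyl_fit <- function(direction, point = c(0, 0, -100)) {
  structure(list(axis_point = point, axis_direction = direction, radius = 5,
                 length = 100, rms_residual = 0), class = "fitted_cylinder")
}

test_that("build_acs yields a right-handed orthonormal frame at the joint center", {
  acs <- build_acs(make_sphere_fit(c(0, 0, 0), 2),
                   make_sphere_fit(c(0, 0, 0), 1.8),
                   make_cyl_fit(c(0, 0, 1)),  # canonical +Z; line along Z
                   ground_normal = c(0, 0, 1))
  expect_equal(acs$origin, c(0, 0, 0))
  expect_equal(unname(acs$axes[, "z"]), c(0, 0, 1))
  expect_equal(crossprod(acs$axes), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(acs$axes), 1, tolerance = 1e-9)
  xyz <- acs$axes
  cross_xy <- c(xyz[2, 1] * xyz[3, 2] - xyz[3, 1] * xyz[2, 2],
                xyz[3, 1] * xyz[1, 2] - xyz[1, 1] * xyz[3, 2],
                xyz[1, 1] * xyz[2, 2] - xyz[2, 1] * xyz[1, 2])
  expect_equal(cross_xy, unname(xyz[, 3]), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(acs$rotation_order, "XYZ")
})

test_that("build_acs rejects unresolvable or non-superimposed setups", {
  expect_error(build_acs(make_sphere_fit(c(0, 0, 0)),
                         make_sphere_fit(c(5, 0, 0)),
                         make_cyl_fit(c(0, 0, 1))),
               "not superimposed")
  expect_error(build_acs(make_sphere_fit(c(0, 0, 0)),
                         make_sphere_fit(c(0, 0, 0)),
                         make_cyl_fit(c(1, 0, 0))),  # lying flat
               "unresolvable")
  # a rearticulation transform substitutes for prior superimposition
  acs <- build_acs(make_sphere_fit(c(0, 0, 0)), make_sphere_fit(c(5, 0, 0)),
                   make_cyl_fit(c(0, 0, 1)),
                   rearticulation = rigid_transform(diag(3), c(-5, 0, 0)))
  expect_equal(acs$origin, c(0, 0, 0))
})

test_that("build_acs is equivariant under a global rotation of its inputs", {
  set.seed(31)
  R <- random_rotation()
  axis <- c(0.1, -0.05, 0.99)
  axis <- axis / sqrt(sum(axis^2))
  acs0 <- build_acs(make_sphere_fit(c(1, 2, 3)), make_sphere_fit(c(1, 2, 3)),
                    make_cyl_fit(axis), ground_normal = c(0, 0, 1),
                    reference_axis = c(1, 0, 0))
  acs1 <- build_acs(make_sphere_fit(as.vector(R %*% c(1, 2, 3))),
                    make_sphere_fit(as.vector(R %*% c(1, 2, 3))),
                    make_cyl_fit(as.vector(R %*% axis)),
                    ground_normal = as.vector(R %*% c(0, 0, 1)),
                    reference_axis = as.vector(R %*% c(1, 0, 0)))
  expect_equal(acs1$origin, as.vector(R %*% acs0$origin), tolerance = 1e-9)
  expect_equal(unname(acs1$axes), unname(R %*% acs0$axes), tolerance = 1e-9)
})

simple_rig <- function() {
  x <- ideal_joint_rig(800)
  x$rig
}

test_that("apply_pose: identity, additivity, composition order", {
  rig <- simple_rig()
  m0 <- apply_pose(rig, pose(0, 0, 0))
  expect_equal(m0$vertices, rig$distal$vertices, tolerance = 1e-12)
  # single-axis additivity: fe 90 twice == fe 180 once
  r90 <- rig
  r90$distal <- apply_pose(rig, pose(fe = 90))
  twice <- apply_pose(r90, pose(fe = 90))
  once <- apply_pose(rig, pose(fe = 180))
  expect_equal(twice$vertices, once$vertices, tolerance = 1e-9)
  # composition order is pinned: XYZ differs from applying Z first
  A <- rig$acs$axes
  p <- pose(90, 45, 60)
  vx <- apply_pose(rig, p)$vertices
  Rwrong <- romap:::rot_x_deg(90) %*% romap:::rot_y_deg(45) %*%
    romap:::rot_z_deg(60)
  Mwrong <- A %*% Rwrong %*% t(A)
  o <- rig$acs$origin
  vwrong <- sweep(sweep(rig$distal$vertices, 2, o) %*% t(Mwrong), 2, o, "+")
  expect_gt(max(abs(vx - vwrong)), 1)
})

test_that("apply_pose matches the homogeneous-matrix oracle on random poses", {
  rig <- simple_rig()
  set.seed(3)
  worst <- 0
  for (i in 1:250) {
    p <- pose(runif(1, -180, 180), runif(1, -180, 180), runif(1, -180, 180),
              offset = runif(3, -3, 3))
    pav <- sample(c(TRUE, FALSE), 1)
    got <- apply_pose(rig, p, pivot_at_offset = pav)$vertices
    want <- pose_oracle_vertices(rig, p, pivot_at_offset = pav)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("apply_pose preserves pairwise distances", {
  rig <- simple_rig()
  set.seed(33)
  idx <- sample(nrow(rig$distal$vertices), 40)
  d0 <- as.matrix(dist(rig$distal$vertices[idx, ]))
  for (p in list(pose(30, -60, 110), pose(-90, 45, 5, offset = c(1, -2, 0.5)))) {
    d1 <- as.matrix(dist(apply_pose(rig, p)$vertices[idx, ]))
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("rig configurations round-trip through JSON", {
  rig <- simple_rig()
  path <- withr::local_tempfile(fileext = ".json")
  save_rig_config(rig, path)
  back <- load_rig_config(path, rig$proximal, rig$distal)
  expect_equal(back$acs$origin, rig$acs$origin, tolerance = 1e-12)
  expect_equal(unname(back$acs$axes), unname(rig$acs$axes), tolerance = 1e-12)
})
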