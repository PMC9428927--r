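# Sphere/cylinder fitting, rearticulation and joint spacing.

test_that("fit_sphere recovers exact and noisy spheres", {
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  f <- fit_sphere(octa)
  expect_equal(f$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_equal(f$rms_residual, 0, tolerance = 1e-12)

  set.seed(101)
  n <- 500
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 17.5, 2, c(10, -5, 3), "+") +
    matrix(rnorm(3 * n, 0, 0.1), ncol = 3)
  f <- fit_sphere(pts)
  expect_lt(max(abs(f$center - c(10, -5, 3))), 0.05)
  expect_lt(abs(f$radius - 17.5), 0.05)
})

test_that("geometric refinement agrees with the algebraic solution on noiseless data", {
  set.seed(5)
  u <- matrix(rnorm(900), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 9.25, 2, c(-2, 4, 1), "+")
  # algebraic closed form as the oracle
  A <- cbind(2 * pts, 1)
  b <- rowSums(pts^2)
  sol <- qr.solve(A, b)
  alg_center <- sol[1:3]
  alg_radius <- sqrt(sol[4] + sum(alg_center^2))
  f <- fit_sphere(pts)
  expect_lt(max(abs(f$center - alg_center)), 1e-9)
  expect_lt(abs(f$radius - alg_radius), 1e-9)
})

test_that("fit_sphere rejects degenerate input", {
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "at least 4")
  flat <- cbind(matrix(runif(40), ncol = 2), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("fit_sphere is equivariant under rigid motion", {
  set.seed(11)
  u <- matrix(rnorm(600), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 5, 2, c(1, 2, 3), "+") + matrix(rnorm(600, 0, 0.05),
                                                   ncol = 3)
  f0 <- fit_sphere(pts)
  R <- random_rotation()
  t <- c(-4, 7, 2)
  f1 <- fit_sphere(sweep(pts %*% t(R), 2, t, "+"))
  expect_lt(max(abs(f1$center - (as.vector(R %*% f0$center) + t))), 1e-9)
  expect_lt(abs(f1$radius - f0$radius), 1e-9)
})

test_that("fit_cylinder recovers exact and noisy cylinders", {
  set.seed(21)
  z <- runif(200, -10, 10)
  phi <- runif(200, 0, 2 * pi)
  pts <- cbind(5 * cos(phi), 5 * sin(phi), z)
  f <- fit_cylinder(pts)
  expect_lt(abs(f$radius - 5), 1e-6)
  expect_lt(acos(min(1, abs(sum(f$axis_direction * c(0, 0, 1))))), 1e-6)
  expect_equal(f$length, diff(range(z)), tolerance = 1e-5)

  noisy <- pts + matrix(rnorm(600, 0, 0.05), ncol = 3)
  fn <- fit_cylinder(noisy)
  expect_lt(abs(fn$radius - 5), 0.02)
})

test_that("cylinder axis sign is canonical (positive Z component)", {
  set.seed(22)
  z <- runif(300, -20, 20)
  phi <- runif(300, 0, 2 * pi)
  # axis deliberately pointing down
  pts <- cbind(3 * cos(phi), 3 * sin(phi), z)
  pts_flipped <- pts
  pts_flipped[, 3] <- -pts_flipped[, 3]
  f1 <- fit_cylinder(pts)
  f2 <- fit_cylinder(pts_flipped)
  expect_gt(f1$axis_direction[3], 0)
  expect_gt(f2$axis_direction[3], 0)
  expect_error(fit_cylinder(cbind(1:10, 1:10, 1:10)), "collinear")
})

test_that("rearticulate superimposes sphere centers", {
  s0 <- structure(list(center = c(0, 0, 0), radius = 2, rms_residual = 0),
                  class = "fitted_sphere")
  s1 <- structure(list(center = c(3, 4, 0), radius = 2, rms_residual = 0),
                  class = "fitted_sphere")
  tr <- rearticulate(s0, s1)
  expect_equal(tr$translation, c(3, 4, 0))
  expect_equal(sqrt(sum(tr$translation^2)), 5)
  expect_equal(rearticulate(s1, s1)$translation, c(0, 0, 0))
  # refit oracle: transform the mesh, refit, centers coincide
  sph <- uv_sphere_mesh(center = c(30, 0, 10), radius = 6)
  fit0 <- fit_sphere(sph$vertices)
  target <- structure(list(center = c(1, 2, 3), radius = 6,
                           rms_residual = 0), class = "fitted_sphere")
  moved <- transform_mesh(sph, rearticulate(fit0, target))
  refit <- fit_sphere(moved$vertices)
  expect_lt(max(abs(refit$center - target$center)), 1e-6)
  # rearticulate there and back is the identity
  back <- rearticulate(target, fit0)
  expect_equal(back$translation + rearticulate(fit0, target)$translation,
               c(0, 0, 0))
})

test_that("joint spacing is the radii difference", {
  cup <- structure(list(center = c(0, 0, 0), radius = 20.0,
                        rms_residual = 0), class = "fitted_sphere")
  head <- structure(list(center = c(0, 0, 0), radius = 17.552,
                         rms_residual = 0), class = "fitted_sphere")
  sp <- joint_spacing_from_radii(cup, head)
  expect_equal(sp$value, 2.448)
  expect_equal(sp$source, "radii_difference")
  expect_equal(joint_spacing_from_radii(cup, cup)$value, 0)
  expect_error(joint_spacing_from_radii(head, cup), "non-physical")
})

test_that("fitted radii recover the synthetic generator's ground truth within 1%", {
  x <- ideal_joint_rig(2000)
  truth <- x$joint$truth
  expect_lt(abs(x$head$radius - truth$head_radius) / truth$head_radius, 0.01)
  expect_lt(abs(x$cup$radius - truth$cup_radius) / truth$cup_radius, 0.01)
  sp <- joint_spacing_from_radii(x$cup, x$head)
  expect_lt(abs(sp$value - truth$joint_spacing), 0.01 * truth$joint_spacing)
})
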