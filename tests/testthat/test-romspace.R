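# Cosine-corrected shape space, alpha-shape volumes and map comparison.

fake_map <- function(grid, viable) {
  structure(list(grid = grid, regime = "3dof", poses = generate_grid(grid),
                 viable = viable,
                 n_offsets_clear = as.integer(viable), offsets = NULL,
                 clear_matrix = NULL, static_offset = NULL,
                 offset_sphere = NULL, tol = 0),
            class = "rom_map")
}

test_that("cosine correction scales abad by cos(fe)", {
  df <- data.frame(abad = c(30, 30, -40), fe = c(0, 90, 60),
                   lar = c(50, 50, 10))
  cc <- cosine_correct(df)
  expect_equal(unname(cc$points[1, ]), c(30, 0, 50))
  expect_equal(unname(cc$points[2, ]), c(30 * cos(pi / 2), 90, 50))
  expect_equal(unname(cc$points[2, "abad"]), 0, tolerance = 1e-12)
  expect_equal(unname(cc$points[3, ]), c(-40 * 0.5, 60, 10))
  # identity on the fe = 0 plane
  flat <- data.frame(abad = runif(20, -90, 90), fe = 0,
                     lar = runif(20, -180, 180))
  expect_equal(unname(cosine_correct(flat)$points),
               unname(as.matrix(flat[, c("abad", "fe", "lar")])))
  expect_error(cosine_correct(data.frame(abad = numeric(), fe = numeric(),
                                         lar = numeric())), "no viable")
})

test_that("correction contracts the convex hull (|cos| <= 1)", {
  set.seed(5)
  for (i in 1:50) {
    df <- data.frame(abad = runif(30, -90, 90), fe = runif(30, -170, 170),
                     lar = runif(30, -180, 180))
    v_raw <- alpha_volume(cosine_correct(df, "none"), Inf)$volume
    v_cor <- alpha_volume(cosine_correct(df), Inf)$volume
    expect_lte(v_cor, v_raw + 1e-9 * v_raw)
  }
})

test_that("alpha volumes: cube, filled grid, convex-hull limit", {
  cube <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  r <- alpha_volume(cube, 100)
  expect_equal(r$volume, 1000, tolerance = 1e-6)
  expect_equal(r$n_components, 1)
  # dense 5-degree grid filling a 50^3 box
  g <- as.matrix(expand.grid(seq(0, 50, 5), seq(0, 50, 5), seq(0, 50, 5)))
  rg <- alpha_volume(g, 10)
  expect_lt(abs(rg$volume - 125000) / 125000, 0.05)
  expect_equal(rg$n_components, 1)
  # alpha -> Inf reproduces the convex hull; oracle = scipy ConvexHull on
  # the identical (seeded) cloud, frozen: 127.6813090371
  set.seed(42)
  pts <- matrix(rnorm(3000), ncol = 3)
  ri <- alpha_volume(pts, Inf)
  expect_lt(abs(ri$volume - 127.6813090371) / 127.6813090371, 1e-6)
  expect_equal(ri$volume, ri$hull_volume)
})

test_that("alpha volume is monotone in alpha and bounded by the hull", {
  set.seed(19)
  pts <- matrix(runif(900, 0, 50), ncol = 3)
  alphas <- c(3, 6, 10, 20, 40, Inf)
  vols <- vapply(alphas, function(a) alpha_volume(pts, a)$volume, 0.0)
  expect_true(all(diff(vols) >= -1e-9))
  hull <- alpha_volume(pts, Inf)$hull_volume
  expect_true(all(vols <= hull + 1e-9 * hull))
})

test_that("alpha shapes separate disjoint pose islands", {
  set.seed(23)
  blob <- matrix(runif(600, 0, 10), ncol = 3)
  shifted <- blob
  shifted[, 1] <- shifted[, 1] + 100
  r <- alpha_volume(rbind(blob, shifted), 15)
  expect_equal(r$n_components, 2)
})

test_that("alpha volume rejects degenerate input", {
  expect_error(alpha_volume(matrix(runif(9), 3, 3), 1), "at least 4")
  flat <- cbind(matrix(runif(40), ncol = 2), 2)
  expect_error(alpha_volume(flat, 1), "coplanar")
  expect_error(alpha_volume(matrix(runif(30), ncol = 3), -1), "alpha")
})

test_that("compare_maps reports set arithmetic and extents", {
  g <- pose_grid(fe_range = c(-60, 60), abad_range = c(-30, 30),
                 lar_range = c(-90, 90), step = 30)
  n <- grid_size(g)
  stopifnot(n >= 80)
  va <- rep(FALSE, n)
  va[1:60] <- TRUE
  vb <- rep(FALSE, n)
  vb[21:80] <- TRUE
  a <- fake_map(g, va)
  b <- fake_map(g, vb)
  cm <- compare_maps(a, b)
  expect_equal(cm$intersection, 40)
  expect_equal(cm$only_a, 20)
  expect_equal(cm$only_b, 20)
  expect_equal(cm$jaccard, 40 / 80)
  # symmetric under swap
  cm2 <- compare_maps(b, a)
  expect_equal(cm2$intersection, cm$intersection)
  expect_equal(cm2$only_a, cm$only_b)
  # identical maps
  cid <- compare_maps(a, a)
  expect_equal(cid$jaccard, 1)
  expect_equal(cid$only_a + cid$only_b, 0)
  # empty vs non-empty
  cz <- compare_maps(a, fake_map(g, rep(FALSE, n)))
  expect_equal(cz$jaccard, 0)
  # mismatched grids refused
  g2 <- pose_grid(fe_range = c(-60, 60), abad_range = c(-30, 30),
                  lar_range = c(-60, 60), step = 15)
  expect_error(compare_maps(a, fake_map(g2, rep(FALSE, grid_size(g2)))),
               "different grids")
})

test_that("volume ratios reproduce the reference-table percentages", {
  ref <- read.csv(system.file("extdata", "reference_rom_volumes.csv",
                              package = "romap"), comment.char = "#")
  vol <- setNames(ref$volume_deg3, ref$simulation)
  expect_equal(volume_ratio(vol["1"], vol["8"]), 18.61)
  expect_equal(volume_ratio(vol["2"], vol["8"]), 29.21)
  expect_equal(volume_ratio(vol["1"], vol["7"]), 26.20)
  expect_equal(volume_ratio(vol["2"], vol["7"]), 41.13)
  expect_equal(volume_ratio(5, 5), 100)
  expect_error(volume_ratio(1, 0), "> 0")
})

test_that("corrected clouds export as PLY point clouds", {
  df <- data.frame(abad = c(0, 10, 20, 5), fe = c(0, 30, -20, 10),
                   lar = c(0, 5, 10, -5))
  cc <- cosine_correct(df)
  path <- withr::local_tempfile(fileext = ".ply")
  export_cloud_ply(cc, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^element vertex", lines)), 1)
  expect_equal(length(lines) - which(lines == "end_header"), 4)
})
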