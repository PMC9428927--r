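# Joint-angle traces and their comparison against viable-pose envelopes.

test_that("traces load from CSV and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,fe,abad,lar", "0,10,1,2", "0.01,12,2,1"), path)
  tr <- load_trace(path)
  expect_equal(nrow(tr$frames), 2)
  expect_equal(tr$frames$fe, c(10, 12))
  # non-monotone time
  writeLines(c("time,fe,abad,lar", "0.01,10,1,2", "0,12,2,1"), path)
  expect_error(load_trace(path), "strictly increasing")
  writeLines(c("time,fe,abad", "0,10,1"), path)
  expect_error(load_trace(path), "needs columns")
})

test_that("gait traces round-trip through CSV", {
  tr <- make_gait_trace(c(fe = 40, abad = 10, lar = 8), n_frames = 60,
                        seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  save_trace(tr, path)
  back <- load_trace(path)
  expect_equal(back$frames$fe, tr$frames$fe, tolerance = 1e-9)
  expect_equal(back$frames$time, tr$frames$time, tolerance = 1e-9)
  expect_equal(back$condition, tr$condition)
})

grid27 <- pose_grid(fe_range = c(-5, 5), abad_range = c(-5, 5),
                    lar_range = c(-5, 5), step = 5)

map27 <- function(viable) {
  structure(list(grid = grid27, regime = "3dof",
                 poses = generate_grid(grid27), viable = viable,
                 n_offsets_clear = as.integer(viable), offsets = NULL,
                 clear_matrix = NULL, static_offset = NULL,
                 offset_sphere = NULL, tol = 0), class = "rom_map")
}

test_that("trace viability against full, empty and constructed maps", {
  # snapped cells: (0,0,0), (0,5,0), (5,0,0), (0,-5,0), (0,0,5)
  tr <- joint_angle_trace(data.frame(
    time = seq(0, 0.4, by = 0.1),
    fe = c(0, 4, 0, -4, 0), abad = c(0, 1, 4, -1, 2),
    lar = c(0, 0, 1, -2, 4)))
  full <- map27(rep(TRUE, 27))
  expect_equal(trace_viability(tr, full)$fraction_viable, 1.0)
  empty <- map27(rep(FALSE, 27))
  expect_equal(trace_viability(tr, empty)$fraction_viable, 0.0)
  # two frames constructed to sit in unviable cells
  viable <- rep(TRUE, 27)
  poses <- generate_grid(grid27)
  viable[poses$abad == 0 & poses$fe == 5 & poses$lar == 0] <- FALSE  # frame 2
  viable[poses$abad == 5 & poses$fe == 0 & poses$lar == 0] <- FALSE  # frame 3
  rep3 <- trace_viability(tr, map27(viable))
  expect_equal(rep3$fraction_viable, 3 / 5)
  expect_equal(sum(!rep3$frames$viable), 2)
  expect_equal(rep3$excursions, data.frame(first_frame = 2, last_frame = 3))
})

test_that("snapping stays within half a grid step and breaks ties toward zero", {
  g <- pose_grid(fe_range = c(-20, 20), abad_range = c(-20, 20),
                 lar_range = c(-20, 20), step = 5)
  m <- structure(list(grid = g, regime = "3dof", poses = generate_grid(g),
                      viable = rep(TRUE, grid_size(g)),
                      n_offsets_clear = rep(1L, grid_size(g)),
                      offsets = NULL, clear_matrix = NULL,
                      static_offset = NULL, offset_sphere = NULL, tol = 0),
                 class = "rom_map")
  set.seed(41)
  tr <- joint_angle_trace(data.frame(time = 1:50 / 50,
                                     fe = runif(50, -20, 20),
                                     abad = runif(50, -20, 20),
                                     lar = runif(50, -20, 20)))
  rep <- trace_viability(tr, m)
  expect_true(all(abs(rep$frames$snapped_fe - rep$frames$fe) <= 2.5 + 1e-9))
  expect_true(all(abs(rep$frames$snapped_abad - rep$frames$abad) <= 2.5 + 1e-9))
  # exact ties go toward zero
  tie <- joint_angle_trace(data.frame(time = c(0, 1), fe = c(2.5, -2.5),
                                      abad = c(7.5, -7.5), lar = c(12.5, 0)))
  rt <- trace_viability(tie, m)
  expect_equal(rt$frames$snapped_fe, c(0, 0))
  expect_equal(rt$frames$snapped_abad, c(5, -5))
  expect_equal(rt$frames$snapped_lar, c(10, 0))
})

test_that("fraction viable is invariant to uniform time rescaling", {
  tr <- make_gait_trace(c(fe = 15, abad = 5, lar = 5), n_frames = 40,
                        seed = 4)
  g <- pose_grid(fe_range = c(-20, 20), abad_range = c(-10, 10),
                 lar_range = c(-10, 10), step = 5)
  set.seed(43)
  viable <- runif(grid_size(g)) < 0.5
  m <- structure(list(grid = g, regime = "3dof", poses = generate_grid(g),
                      viable = viable,
                      n_offsets_clear = as.integer(viable), offsets = NULL,
                      clear_matrix = NULL, static_offset = NULL,
                      offset_sphere = NULL, tol = 0), class = "rom_map")
  f1 <- trace_viability(tr, m)$fraction_viable
  tr2 <- tr
  tr2$frames$time <- tr$frames$time * 100
  f2 <- trace_viability(tr2, m)$fraction_viable
  expect_equal(f1, f2)
  expect_gte(f1, 0)
  expect_lte(f1, 1)
})

test_that("frames outside the grid are flagged and unviable", {
  g <- pose_grid(fe_range = c(-10, 10), abad_range = c(-10, 10),
                 lar_range = c(-10, 10), step = 5)
  m <- structure(list(grid = g, regime = "3dof", poses = generate_grid(g),
                      viable = rep(TRUE, grid_size(g)),
                      n_offsets_clear = rep(1L, grid_size(g)),
                      offsets = NULL, clear_matrix = NULL,
                      static_offset = NULL, offset_sphere = NULL, tol = 0),
                 class = "rom_map")
  tr <- joint_angle_trace(data.frame(time = c(0, 1), fe = c(0, 90),
                                     abad = c(0, 0), lar = c(0, 0)))
  rep <- trace_viability(tr, m)
  expect_equal(rep$frames$in_range, c(TRUE, FALSE))
  expect_equal(rep$frames$viable, c(TRUE, FALSE))
  expect_equal(rep$fraction_viable, 0.5)
})
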