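test_that("disjoint bright discs are segmented as separate particles", {
  img <- matrix(0, 128, 128)
  img[outer(1:128, 1:128,
            function(i, j) (i - 35)^2 + (j - 35)^2 <= 15^2)] <- 0.8
  img[90:120, 90:120] <- 0.8
  ps <- segment(calibrated_image(img, 1), min_area_um2 = 100,
                max_area_um2 = 1e5)
  expect_equal(ps$n_particles, 2)
})

test_that("the minimum-area gate removes small particles", {
  img <- matrix(0, 96, 96)
  img[outer(1:96, 1:96,
            function(i, j) (i - 48)^2 + (j - 48)^2 <= 9^2)] <- 0.9
  # disc area ~254 um^2 at 1 um/px
  ps <- segment(calibrated_image(img, 1), min_area_um2 = 500,
                max_area_um2 = 1e5)
  expect_equal(ps$n_particles, 0)
  ps2 <- segment(calibrated_image(img, 1), min_area_um2 = 100,
                 max_area_um2 = 1e5)
  expect_equal(ps2$n_particles, 1)
})

test_that("raising min_area_um2 never increases the particle count", {
  sc <- rod_scene(100, 25, noise_sd = 0.05, seed = 3)
  counts <- vapply(c(0, 200, 500, 1500, 2500), function(a)
    segment(sc$image, min_area_um2 = a, max_area_um2 = 1e5)$n_particles,
    0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("labels are always consecutive 1..n", {
  specs <- sample_population(8, "control", c(intact_rod = 1), seed = 4,
                             orientation_range = c(-10, 10))
  specs <- place_specs(specs, c(1024, 1024), 0.65, seed = 4)
  sc <- render_scene(c(1024, 1024), 0.65, specs, noise_sd = 0.05, seed = 4)
  ps <- segment(sc$image)
  labs <- sort(unique(as.integer(ps$label_map)))
  expect_equal(labs, 0:ps$n_particles)
})

test_that("a 50-rod synthetic field is recovered cell for cell", {
  specs <- sample_population(50, "control", c(intact_rod = 1), seed = 5,
                             orientation_range = c(-10, 10))
  specs <- place_specs(specs, c(2048, 2048), 0.65, seed = 6)
  sc <- render_scene(c(2048, 2048), 0.65, specs, noise_sd = 0.05, seed = 7)
  ps <- segment(sc$image)
  expect_equal(ps$n_particles, 50)
  jac <- vapply(1:50, function(k) {
    tm <- sc$label_map == k
    ids <- ps$label_map[tm]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(0)
    pid <- as.integer(names(which.max(table(ids))))
    pm <- ps$label_map == pid
    sum(tm & pm) / sum(tm | pm)
  }, 0)
  expect_true(all(jac >= 0.9))
})

test_that("edge exclusion drops border-touching particles", {
  sp_edge <- cell_spec("intact_rod", 80, 20, 0, NA, center = c(20, 40))
  sp_in <- cell_spec("intact_rod", 80, 20, 0, NA, center = c(100, 100))
  sc <- render_scene(c(256, 256), 0.65, list(sp_edge, sp_in),
                     noise_sd = 0, seed = 1)
  all_ps <- segment(sc$image, min_area_um2 = 100, max_area_um2 = 1e5)
  kept <- segment(sc$image, min_area_um2 = 100, max_area_um2 = 1e5,
                  exclude_edges = TRUE)
  expect_equal(all_ps$n_particles, 2)
  expect_equal(kept$n_particles, 1)
})

test_that("hole filling closes enclosed background", {
  img <- matrix(0, 80, 80)
  img[20:60, 20:60] <- 0.9
  img[35:45, 35:45] <- 0          # enclosed hole
  ps <- segment(calibrated_image(img, 1), min_area_um2 = 100,
                max_area_um2 = 1e5, fill_holes = TRUE)
  expect_equal(sum(ps$label_map == 1), 41^2)
  ps2 <- segment(calibrated_image(img, 1), min_area_um2 = 100,
                 max_area_um2 = 1e5, fill_holes = FALSE)
  expect_equal(sum(ps2$label_map == 1), 41^2 - 11^2)
})

test_that("degenerate images are rejected or yield empty sets", {
  blank <- calibrated_image(matrix(0.01, 64, 64) +
                              matrix(runif(64^2, 0, 1e-3), 64), 1)
  expect_warning(ps <- segment(blank, threshold_method = "fixed",
                               fixed_threshold = max(blank$pixels),
                               min_area_um2 = 100, max_area_um2 = 1e6),
                 "empty")
  expect_equal(ps$n_particles, 0)
  flat <- calibrated_image(matrix(0.5, 64, 64), 1)
  expect_error(segment(flat), "otsu")
  img <- calibrated_image(matrix(runif(64^2), 64), 1)
  expect_error(segment(img, threshold_method = "fixed",
                       fixed_threshold = 7),
               "intensity range")
})

test_that("fixed thresholding honours the given level", {
  img <- matrix(0, 64, 64)
  img[10:30, 10:30] <- 0.4
  img[40:60, 40:60] <- 0.8
  ps <- segment(calibrated_image(img, 1), threshold_method = "fixed",
                fixed_threshold = 0.6, min_area_um2 = 10,
                max_area_um2 = 1e5)
  expect_equal(ps$n_particles, 1)
  ps2 <- segment(calibrated_image(img, 1), threshold_method = "fixed",
                 fixed_threshold = 0.2, min_area_um2 = 10,
                 max_area_um2 = 1e5)
  expect_equal(ps2$n_particles, 2)
})

test_that("8-connectivity joins diagonally touching foreground", {
  img <- matrix(0, 64, 64)
  for (i in 10:40) img[i, i] <- 0.9          # diagonal line
  ps <- segment(calibrated_image(img, 1), min_area_um2 = 1,
                max_area_um2 = 1e5, fill_holes = FALSE)
  expect_equal(ps$n_particles, 1)
})
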