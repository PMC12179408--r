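test_that("rendered rod area matches the analytic capsule area", {
  sc <- rod_scene(137.81, 28.53, orientation_deg = 20)
  expect_equal(max(sc$label_map), 1)
  drawn <- sum(sc$label_map == 1) * 0.65^2
  expect_lt(abs(drawn / capsule_area(137.81, 28.53) - 1), 0.03)
})

test_that("geometry conservation holds across classes and angles", {
  for (th in c(0, 33, 90, 147)) {
    sc <- rod_scene(100, 24, orientation_deg = th)
    drawn <- sum(sc$label_map == 1) * 0.65^2
    expect_lt(abs(drawn / capsule_area(100, 24) - 1), 0.03)
  }
  sp <- cell_spec("rounded", 40, 40, 0, NA, center = c(40, 40))
  sc <- render_scene(c(128, 128), 0.65, list(sp), noise_sd = 0, seed = 1)
  drawn <- sum(sc$label_map == 1) * 0.65^2
  expect_lt(abs(drawn / (pi * 20^2) - 1), 0.03)
})

test_that("empty spec list renders an empty scene", {
  sc <- render_scene(c(64, 64), 0.65, list(), noise_sd = 0, seed = 1)
  expect_equal(nrow(sc$truth), 0)
  expect_true(all(sc$label_map == 0))
  expect_true(all(sc$image$pixels == 0))
})

test_that("rendering is bit-identical for a fixed spec and seed", {
  sp <- cell_spec("touching_pair", 120, 26, 40, 1.8, center = c(70, 70))
  a <- render_scene(c(220, 220), 0.65, list(sp), noise_sd = 0.05, seed = 9)
  b <- render_scene(c(220, 220), 0.65, list(sp), noise_sd = 0.05, seed = 9)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$label_map, b$label_map)
  c <- render_scene(c(220, 220), 0.65, list(sp), noise_sd = 0.05, seed = 10)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("overlap ties go to the lower spec index", {
  s1 <- cell_spec("rounded", 30, 30, 0, NA, center = c(40, 40))
  s2 <- cell_spec("rounded", 30, 30, 0, NA, center = c(55, 40))
  sc <- render_scene(c(128, 96), 0.65, list(s1, s2), noise_sd = 0, seed = 1)
  # overlapping strip must belong to label 1
  mid <- sc$label_map[, round(47.5 / 0.65)]
  expect_true(all(mid[mid > 0] == 1))
})

test_that("class composition is exact under largest-remainder allocation", {
  specs <- sample_population(100, "control",
                             c(intact_rod = 0.97, rounded = 0.03), seed = 2)
  cls <- vapply(specs, function(s) s$cell_class, "")
  expect_equal(sum(cls == "intact_rod"), 97)
  expect_equal(sum(cls == "rounded"), 3)

  specs1 <- sample_population(1, "control", c(intact_rod = 1), seed = 2)
  expect_equal(specs1[[1]]$cell_class, "intact_rod")

  for (n in c(7, 23, 100)) {
    specs <- sample_population(n, "control",
                               c(intact_rod = 0.70, touching_pair = 0.15,
                                 rounded = 0.10, fragment = 0.05),
                               seed = n)
    cls <- table(factor(vapply(specs, function(s) s$cell_class, ""),
                        levels = c("intact_rod", "touching_pair",
                                   "rounded", "fragment")))
    expect_equal(sum(cls), n)
    alloc <- cardiomorph:::largest_remainder(
      n, c(intact_rod = 0.70, touching_pair = 0.15, rounded = 0.10,
           fragment = 0.05))
    expect_equal(as.integer(cls), as.integer(alloc))
  }
})

test_that("population sampling recovers its own parameters", {
  specs <- sample_population(2000, "control", c(intact_rod = 1), seed = 3)
  L <- vapply(specs, function(s) s$length_um, 0)
  W <- vapply(specs, function(s) s$width_um, 0)
  expect_lt(abs(mean(L) - 139.42), 3 * 33.06 / sqrt(2000))
  expect_lt(abs(mean(W) - 28.78), 3 * 7.93 / sqrt(2000))
  expect_true(all(L >= W))
  expect_true(all(W >= 5))
})

test_that("population sampling validates its inputs", {
  expect_error(sample_population(10, "control", c(intact_rod = 0.5)),
               "sum to 1")
  expect_error(sample_population(10,
                                 list(length_um = c(-5, 1),
                                      width_um = c(10, 1)),
                                 c(intact_rod = 1)),
               "negative mean")
  expect_error(render_scene(c(64, 64), -1, list()), "positive")
})

test_that("specs reaching outside the field are clipped and flagged", {
  sp <- cell_spec("intact_rod", 120, 25, 0, NA, center = c(10, 40))
  sc <- render_scene(c(128, 128), 0.65, list(sp), noise_sd = 0, seed = 1)
  expect_true(sc$truth$clipped[1])
  inside <- cell_spec("intact_rod", 60, 20, 0, NA, center = c(41, 41))
  sc2 <- render_scene(c(128, 128), 0.65, list(inside), noise_sd = 0,
                      seed = 1)
  expect_false(sc2$truth$clipped[1])
})

test_that("cuboid debug stack records the exact analytic volume", {
  cs <- cuboid_stack(c(20, 10, 5), c(0.5, 0.5, 1.0))
  expect_equal(cs$truth$volume_um3, 250)
  expect_equal(sum(cs$stack > 0) * prod(cs$voxel_um), 250)
})

test_that("z-stack rendering is deterministic and volume-consistent", {
  sp <- cell_spec("intact_rod", 140, 30, 0, 1.8)
  a <- render_stack(sp, seed = 4, noise_sd = 0.02)
  b <- render_stack(sp, seed = 4, noise_sd = 0.02)
  expect_identical(a$stack, b$stack)
  # depth_ratio geometry: analytic volume vs brute-force voxel count
  clean <- render_stack(sp, seed = 4, noise_sd = 0)
  vox <- sum(clean$stack > 0) * prod(clean$voxel_um)
  expect_lt(abs(vox / clean$truth$volume_um3 - 1), 0.05)
  expect_equal(clean$truth$volume_um3, pi / 4 * 30 * 15 * 140)
})

test_that("a target volume overrides the default depth ratio", {
  sp <- cell_spec("intact_rod", 139.42, 28.78, 0, 1.8,
                  volume_um3 = 35368.88)
  st <- render_stack(sp, seed = 1)
  expect_equal(st$truth$volume_um3, 35368.88, tolerance = 1e-12)
  vox <- sum(st$stack > 0) * prod(st$voxel_um)
  expect_lt(abs(vox / 35368.88 - 1), 0.05)
})

test_that("scene TIFF round-trips with its calibration", {
  dir <- withr::local_tempdir()
  sc <- rod_scene(80, 20, noise_sd = 0.03)
  write_scene(sc, dir, "s")
  img <- read_image_tiff(file.path(dir, "s.tif"))
  expect_s3_class(img, "calibrated_image")
  expect_equal(img$pixel_size_um, 0.65)
  expect_equal(dim(img$pixels), dim(sc$image$pixels))
  # 16-bit quantization bounds the round-trip error
  expect_lt(max(abs(img$pixels - pmin(pmax(sc$image$pixels, 0), 1))),
            1 / 65535 + 1e-9)
  truth <- read.csv(file.path(dir, "s_truth.csv"))
  expect_equal(nrow(truth), 1)
})
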