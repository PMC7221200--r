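# Water-surface masking, color thresholding and area measurement.

flat_image <- function(color, h = 120, w = 120, ...) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- color[ch]
  dish_image(px, ...)
}

# independent reference disc used by the config-mode mask test
disc_mask_ref <- function(h, w, c0, r) {
  outer(seq_len(h), seq_len(w),
        function(i, j) (i - c0[1])^2 + (j - c0[2])^2 <= r^2)
}

test_that("config-mode water mask uses the exact circle geometry", {
  geom <- list(center_px = c(60, 60), radius_px = 50,
               metres_per_px = 0.0725 / 50)
  img <- flat_image(c(70, 110, 165), geometry = geom)
  w <- detect_water_mask(img)
  expect_equal(w$source, "config")
  # 145-mm inner diameter: water area = pi x 0.0725^2 ~ 1.6513e-2 m^2
  expect_equal(w$water_area_m2, WATER_AREA_145MM)
  expect_equal(round(w$water_area_m2, 6), 0.016513)
  expect_true(all(which(w$mask) %in% which(disc_mask_ref(120, 120, c(60, 60), 50))))
})

test_that("auto-detection finds the dish circle within 2 px, or errors", {
  scene <- small_scene(seed = 21)
  ser <- generate_dish_series(scene, growth_scenario(4e-4, 0.15))
  img <- as_dish_image(ser[[1]])
  w <- detect_water_mask(img, geometry = NULL,
                         metres_per_px = scene$metres_per_px)
  expect_equal(w$source, "detected")
  expect_lt(max(abs(w$center_px - scene$dish_center_px)), 2)
  expect_lt(abs(w$radius_px - scene$dish_radius_px), 2)

  # all-background image: no dish to find
  bg <- flat_image(c(30, 30, 34))
  expect_error(detect_water_mask(bg, geometry = NULL,
                                 metres_per_px = 1e-3), "no dish found")
  expect_error(detect_water_mask(bg, geometry = NULL), "metres_per_px")
})

test_that("thresholding handles the empty and saturated extremes", {
  geom <- list(center_px = c(60, 60), radius_px = 50, metres_per_px = 1e-3)
  water_only <- flat_image(c(70, 110, 165), geometry = geom)
  w <- detect_water_mask(water_only)
  expect_equal(sum(threshold_fronds(water_only, w)), 0)
  rec <- measure_frond_area(water_only, w)
  expect_equal(rec$frond_area_m2, 0)

  # water surface entirely frond-colored: mask = water mask, full coverage
  all_frond <- flat_image(c(70, 150, 60), geometry = geom)
  mask <- threshold_fronds(all_frond, w)
  expect_identical(mask, w$mask)
  rec <- measure_frond_area(all_frond, w)
  expect_equal(rec$coverage_fraction, 1)
  expect_equal(rec$frond_area_m2, w$water_area_m2)
})

test_that("measured area tracks ground truth on a synthetic dish", {
  scene <- small_scene(seed = 8)
  water_area <- pi * (scene$dish_radius_px * scene$metres_per_px)^2
  gr <- growth_scenario(0.10 * water_area, rgr_per_day = 0,
                        duration_days = 1)
  ser <- generate_dish_series(scene, gr)
  img <- as_dish_image(ser[[1]], attr(ser, "geometry"))
  w <- detect_water_mask(img)
  rec <- measure_frond_area(img, w)
  expect_lt(abs(rec$frond_area_m2 - ser[[1]]$true_area_m2) /
              ser[[1]]$true_area_m2, 0.05)
  expect_equal(rec$coverage_fraction, 0.10, tolerance = 0.01)
})

test_that("monotonicity: adding frond pixels never decreases measured area", {
  geom <- list(center_px = c(60, 60), radius_px = 50, metres_per_px = 1e-3)
  img <- flat_image(c(70, 110, 165), geometry = geom)
  w <- detect_water_mask(img)
  prev <- -1
  for (half in c(5, 15, 30)) {
    px <- img$pixels
    px[(60 - half):(60 + half), (60 - half):(60 + half), 1] <- 70
    px[(60 - half):(60 + half), (60 - half):(60 + half), 2] <- 150
    px[(60 - half):(60 + half), (60 - half):(60 + half), 3] <- 60
    area <- measure_frond_area(dish_image(px, geometry = geom), w)$frond_area_m2
    expect_gte(area, prev)
    prev <- area
  }
})

test_that("scale equivariance: doubling metres_per_px quadruples the area", {
  scene <- small_scene(seed = 4)
  ser <- generate_dish_series(scene, growth_scenario(4e-4, 0.1,
                                                     duration_days = 1))
  geom1 <- attr(ser, "geometry")
  geom2 <- geom1
  geom2$metres_per_px <- 2 * geom1$metres_per_px
  img <- as_dish_image(ser[[1]])
  a1 <- measure_frond_area(img, detect_water_mask(img, geom1))$frond_area_m2
  a2 <- measure_frond_area(img, detect_water_mask(img, geom2))$frond_area_m2
  expect_equal(a2 / a1, 4)
})

test_that("small-blob removal suppresses salt noise only when asked", {
  geom <- list(center_px = c(60, 60), radius_px = 50, metres_per_px = 1e-3)
  px <- array(0, c(120, 120, 3))
  px[, , 1] <- 70; px[, , 2] <- 110; px[, , 3] <- 165
  px[50:59, 50:59, 1] <- 70; px[50:59, 50:59, 2] <- 150; px[50:59, 50:59, 3] <- 60
  px[80, 80, ] <- c(70, 150, 60)  # single-pixel salt
  img <- dish_image(px, geometry = geom)
  w <- detect_water_mask(img)
  expect_equal(sum(threshold_fronds(img, w)), 101)
  th <- frond_thresholds(min_blob_px = 5)
  expect_equal(sum(threshold_fronds(img, w, th)), 100)
})

test_that("dish images survive a PNG round trip", {
  scene <- small_scene(seed = 15)
  ser <- generate_dish_series(scene, growth_scenario(4e-4, 0.2,
                                                     duration_days = 1))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "p100_d1_day0.png")
  write_dish_image(ser[[1]], path,
                   mask_path = file.path(dir, "mask.png"))
  img <- read_dish_image(path, geometry = attr(ser, "geometry"))
  expect_equal(img$dish_id, "p100_d1")
  expect_equal(img$day, 0)
  expect_equal(img$pixels, ser[[1]]$image)
  mask <- png::readPNG(file.path(dir, "mask.png")) > 0.5
  expect_identical(mask, ser[[1]]$mask)
  # measurement is unchanged by the round trip
  w <- detect_water_mask(img)
  expect_equal(measure_frond_area(img, w)$frond_area_m2,
               ser[[1]]$true_area_m2, tolerance = 0.01)
})
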