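# Synthetic-data generators: exact ground truth, determinism, and
# zero-noise round-trips through the analysis stages.

test_that("dish series ground truth follows the analytic growth curve", {
  scene <- small_scene(seed = 3)
  px2 <- scene$metres_per_px^2

  # zero growth: every imaged day has the same ground-truth area
  flat <- growth_scenario(5e-4, rgr_per_day = 0)
  ser <- generate_dish_series(scene, flat)
  areas <- vapply(ser, `[[`, numeric(1), "true_area_m2")
  expect_length(areas, 5)
  expect_true(all(areas == areas[1]))
  expect_equal(areas[1], 5e-4, tolerance = px2 / 5e-4)  # half-pixel quantization

  # doubling in 4 days: final ground truth is 2 FA0
  dbl <- growth_scenario(1e-3, rgr_per_day = log(2) / 4)
  ser <- generate_dish_series(scene, dbl)
  expect_equal(ser[[5]]$true_area_m2, 2e-3, tolerance = 1e-4)
  # ... and the mask itself is the ground truth: pixel count x pixel area
  for (rec in ser) {
    expect_equal(sum(rec$mask) * px2, rec$true_area_m2)
    day_target <- 1e-3 * exp(log(2) / 4 * rec$day)
    expect_lt(abs(rec$true_area_m2 - day_target) / day_target, 0.01)
  }
})

test_that("dish series is bit-reproducible and masks match images", {
  scene <- small_scene(seed = 11)
  gr <- growth_scenario(4e-4, rgr_per_day = 0.2, duration_days = 2)
  a <- generate_dish_series(scene, gr)
  b <- generate_dish_series(scene, gr)
  expect_identical(a, b)
  c <- generate_dish_series(small_scene(seed = 12), gr)
  expect_false(identical(a, c))

  # frond pixels (greenish) are exactly the mask pixels
  rec <- a[[3]]
  green <- rec$image[, , 2] > rec$image[, , 3] &
    rec$image[, , 2] > rec$image[, , 1]
  expect_identical(green & rec$mask, rec$mask)
})

test_that("overflow and degenerate scenarios are rejected up front", {
  scene <- small_scene()
  water_area <- pi * (scene$dish_radius_px * scene$metres_per_px)^2
  too_big <- growth_scenario(water_area * 0.5, rgr_per_day = 0.5)
  expect_error(generate_dish_series(scene, too_big), "overflow")
  tiny <- growth_scenario(1e-12, rgr_per_day = 0)
  expect_error(generate_dish_series(scene, tiny), "below one pixel")
  expect_error(growth_scenario(0, 0.2))
  expect_error(growth_scenario(1e-3, duration_days = 0))
})

test_that("zero-noise fluorescence tables round-trip exactly", {
  scn <- fluor_scenario(ppfd = c(100, 200, 500, 700),
                        true_FvpFmp = c(0.75, 0.62, 0.45, 0.38),
                        true_oneMinusQP = c(1 / 3, 0.3, 0.55, 0.58))
  tab <- generate_fluorescence_table(scn, dishes_per_ppfd = 3)
  expect_equal(nrow(tab), 4 * 3 * 3)
  light <- tab[tab$state == "light", ]
  d <- derive_psii(F = light$F, Fmp = light$Fmp, Fop = light$Fop)
  expect_equal(d$FvpFmp, rep(scn$true_FvpFmp, each = 3), tolerance = 1e-14)
  expect_equal(d$oneMinusQP, rep(scn$true_oneMinusQP, each = 3),
               tolerance = 1e-14)
  dark <- tab[tab$state == "dark_pre", ]
  expect_equal(derive_psii(Fo = dark$Fo, Fm = dark$Fm)$FvFm,
               rep(scn$fvfm_dark_pre, each = 3))

  # deterministic: zero-noise tables are identical across calls
  expect_identical(tab, generate_fluorescence_table(scn, 3))
  noisy <- fluor_scenario(noise_sd = 0.02, seed = 9)
  expect_identical(generate_fluorescence_table(noisy, 2),
                   generate_fluorescence_table(noisy, 2))
})

test_that("zero-efficiency fluorescence rows are degenerate but flagged", {
  scn <- fluor_scenario(ppfd = 100, true_FvpFmp = 0, true_oneMinusQP = 0.5)
  tab <- generate_fluorescence_table(scn, 1)
  light <- tab[tab$state == "light", ]
  expect_equal(light$Fmp, light$Fop)
  d <- derive_psii(F = light$F, Fmp = light$Fmp, Fop = light$Fop)
  expect_true(d$qp_degenerate)
  expect_error(fluor_scenario(true_FvpFmp = 0.9), "max_efficiency")
})

test_that("pigment tables honor configured means, line and recovery sign", {
  # flat scenario: every summary identical across PPFD
  flat_means <- matrix(rep(c(300, 100, 10, 2, 8, 10, 5, 3), each = 4), 4)
  scn <- pigment_scenario(means = flat_means)
  s <- summarize_pigments(generate_pigment_table(scn, 3))
  expect_equal(length(unique(s$vaz)), 1)
  expect_equal(length(unique(s$chl_ab)), 1)

  # configured line: slope -0.3, intercept 0.84 at Z/(V+A+Z) = 0.3 -> 0.75
  means <- matrix(c(300, 100, 12, 2, 6, 10, 5, 3), 1)  # zfrac = 6/20 = 0.3
  scn <- pigment_scenario(ppfd = 500, means = means, fvfm_slope = -0.3,
                          fvfm_intercept = 0.84, zea_recovery_removal = 0)
  tab <- generate_pigment_table(scn, 1)
  expect_equal(unique(tab$dark_fvfm), 0.75)

  # recovery removes zeaxanthin but conserves the V+A+Z pool
  scn <- pigment_scenario(zea_recovery_removal = 0.6, seed = 2)
  tab <- generate_pigment_table(scn, 2)
  for (id in unique(tab$dish_id)) {
    pre <- tab[tab$dish_id == id & tab$recovery == "pre", ]
    post <- tab[tab$dish_id == id & tab$recovery == "post", ]
    expect_lte(post$zea, pre$zea)
    expect_equal(post$viola + post$anthera + post$zea,
                 pre$viola + pre$anthera + pre$zea)
  }

  expect_error(pigment_scenario(means = -flat_means))
  expect_error(generate_pigment_table(scn, 1, samples_per_dish = 3),
               "two samples")
})

test_that("regression on co-generated dark Fv/Fm recovers the configured line", {
  scn <- pigment_scenario(fvfm_slope = -0.3, fvfm_intercept = 0.84)
  tab <- generate_pigment_table(scn, 3)
  zfrac <- tab$zea / (tab$viola + tab$anthera + tab$zea)
  fit <- fit_linear(zfrac, tab$dark_fvfm)
  expect_equal(fit$slope, -0.3)
  expect_equal(fit$intercept, 0.84)
  expect_equal(fit$r_squared, 1)
})
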