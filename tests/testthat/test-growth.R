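# Growth model and photon budget: endpoint RGR, exponential projection,
# the dose integral and light-use efficiency.

test_that("fit_rgr implements the endpoint log-ratio definition", {
  flat <- data.frame(day = 0:4, frond_area_m2 = rep(3e-4, 5))
  expect_equal(fit_rgr(flat)$RGR, 0)

  doubling <- data.frame(day = c(0, 4), frond_area_m2 = c(1e-3, 2e-3))
  fit <- fit_rgr(doubling)
  expect_equal(fit$RGR, log(2) / 4)
  expect_equal(fit$FA0, 1e-3)
  expect_equal(fit$FA4, 2e-3)
  expect_equal(fit$t4, 4)

  # ln-ratio invariance: rescaling all areas by k > 0 leaves RGR unchanged
  for (k in c(0.01, 3, 1e4)) {
    scaled <- doubling
    scaled$frond_area_m2 <- scaled$frond_area_m2 * k
    expect_equal(fit_rgr(scaled)$RGR, fit$RGR)
  }

  # intermediate days do not affect the endpoint fit
  with_middle <- data.frame(day = 0:4,
                            frond_area_m2 = c(1e-3, 5e-3, 2e-4, 9e-4, 2e-3))
  expect_equal(fit_rgr(with_middle)$RGR, fit$RGR)
})

test_that("fit_rgr rejects invalid input", {
  expect_error(fit_rgr(data.frame(day = 1, frond_area_m2 = 1e-3)),
               "two distinct days")
  expect_error(fit_rgr(data.frame(day = c(0, 4), frond_area_m2 = c(0, 1e-3))),
               "positive")
  expect_error(fit_rgr(data.frame(day = c(2, 2),
                                  frond_area_m2 = c(1e-3, 2e-3))),
               "two distinct days")
})

test_that("regression mode recovers an exact exponential and matches lm", {
  days <- 0:4
  areas <- data.frame(day = days, frond_area_m2 = 2e-4 * exp(0.23 * days))
  fit <- fit_rgr(areas, method = "regression")
  expect_equal(fit$RGR, 0.23)
  expect_equal(fit$FA0, 2e-4)

  set.seed(11)
  noisy <- areas
  noisy$frond_area_m2 <- noisy$frond_area_m2 * exp(rnorm(5, 0, 0.05))
  fit <- fit_rgr(noisy, method = "regression")
  lm_slope <- unname(coef(lm(log(frond_area_m2) ~ day, noisy))[2])
  expect_equal(fit$RGR, lm_slope)
})

test_that("project_area evaluates FA0 * exp(RGR t) and is endpoint-consistent", {
  fit <- growth_fit(FA0 = 1e-3, FA4 = 2e-3, t4 = 4)
  expect_equal(project_area(fit, 0), 1e-3)
  expect_equal(project_area(fit, 4), 2e-3)
  fit2 <- growth_fit(FA0 = 1e-3, FA4 = 1e-3 * exp(0.5 * 4), t4 = 4)
  expect_equal(project_area(fit2, 4), 1e-3 * exp(2))
  expect_error(project_area(fit, -1))
})

test_that("photons_received matches the closed form and its zero-growth limit", {
  # zero growth: dose = PPFD * 0.0864 * FA0 * t4
  flat <- growth_fit(FA0 = 1e-3, FA4 = 1e-3, t4 = 4)
  expect_equal(photons_received(flat, 100), 100 * 0.0864 * 1e-3 * 4)
  expect_equal(photons_received(flat, 100), 3.456e-2)
  expect_equal(photons_received(flat, 0), 0)

  # growing dish, checked against adaptive quadrature of the flux
  fit <- growth_fit(FA0 = 1e-3, FA4 = 1e-3 * exp(0.25 * 4), t4 = 4)
  oracle <- integrate(function(t) 100 * 0.0864 * 1e-3 * exp(0.25 * t),
                      0, 4, rel.tol = 1e-12)$value
  expect_equal(photons_received(fit, 100), oracle, tolerance = 1e-10)
  expect_equal(photons_received(fit, 100), 8.64e-3 * expm1(1) / 0.25)
})

test_that("photons_received is continuous across the RGR -> 0 switch and monotone", {
  base <- function(rgr) growth_fit(1e-3, 1e-3 * exp(rgr * 4), t4 = 4)
  near <- vapply(c(-1e-9, -1e-13, 0, 1e-13, 1e-9),
                 function(r) photons_received(base(r), 100), numeric(1))
  expect_true(all(abs(near / near[3] - 1) < 1e-8))

  # strictly increasing in PPFD, FA0, t4 and RGR
  f <- function(ppfd = 100, fa0 = 1e-3, t4 = 4, rgr = 0.2)
    photons_received(growth_fit(fa0, fa0 * exp(rgr * t4), t4), ppfd)
  expect_true(f(ppfd = 200) > f(ppfd = 100))
  expect_true(f(fa0 = 2e-3) > f(fa0 = 1e-3))
  expect_true(f(t4 = 5) > f(t4 = 4))
  expect_true(f(rgr = 0.3) > f(rgr = 0.2))
  expect_true(f(rgr = 0.2) > f(rgr = -0.2))
})

test_that("light_use_efficiency equals the ratio definition and its closed form", {
  flat <- growth_fit(1e-3, 1e-3, 4)
  expect_equal(light_use_efficiency(flat, 100), 0)

  fit <- growth_fit(1e-3, 1e-3 * exp(0.25 * 4), 4)
  expect_equal(light_use_efficiency(fit, 100),
               (fit$FA4 - fit$FA0) / photons_received(fit, 100))
  expect_equal(light_use_efficiency(fit, 100), 0.25 / 8.64)

  # proportionality: 7x the PPFD gives exactly 1/7 the efficiency
  expect_equal(light_use_efficiency(fit, 100) / light_use_efficiency(fit, 700),
               7)
  expect_error(light_use_efficiency(fit, 0), "undefined")
})

test_that("endpoint LUE identity RGR/(0.0864 PPFD) holds on random fits", {
  set.seed(42)
  for (i in 1:50) {
    fa0 <- runif(1, 1e-5, 1e-2)
    rgr <- runif(1, -0.4, 0.9)
    t4 <- runif(1, 1, 10)
    ppfd <- runif(1, 10, 1000)
    fit <- growth_fit(fa0, fa0 * exp(rgr * t4), t4)
    expect_equal(light_use_efficiency(fit, ppfd), rgr / (0.0864 * ppfd),
                 tolerance = 1e-12)
  }
})

test_that("photon_dose_ratio reports percent increase between conditions", {
  a <- growth_fit(1e-3, 1e-3 * exp(0.2 * 4), 4)
  expect_equal(photon_dose_ratio(a, 100, a, 100), 0)
  # equal FA0 and RGR: dose scales with PPFD, 100 -> 700 is +600%
  expect_equal(photon_dose_ratio(a, 100, a, 700), 600)
  # greater RGR at equal PPFD receives more photons
  b <- growth_fit(1e-3, 1e-3 * exp(0.3 * 4), 4)
  expect_gt(photon_dose_ratio(a, 100, b, 100), 0)
  zero <- growth_fit(1e-3, 1e-3, 4)
  expect_error(photon_dose_ratio(zero, 0, a, 100), "zero")
})

test_that("growth_table assembles per-dish budgets", {
  areas <- rbind(
    data.frame(dish_id = "d1", day = c(0, 4), frond_area_m2 = c(1e-3, 2e-3)),
    data.frame(dish_id = "d2", day = c(0, 4), frond_area_m2 = c(1e-3, 3e-3)))
  tab <- growth_table(areas, c(d1 = 100, d2 = 700))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$RGR, c(log(2) / 4, log(3) / 4))
  expect_equal(tab$lue_m2_per_mol, tab$RGR / (0.0864 * tab$ppfd))
  expect_error(growth_table(areas, c(d1 = 100)), "d2")
})
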