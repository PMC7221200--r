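# Seeded synthetic-data generators with known ground truth.
#
# Three generators stand in for the study's raw data so every downstream
# stage has a parameter-recovery test: (1) rendered top-down dish images
# whose total frond area follows an exact exponential growth curve, with
# the ground-truth frond mask returned alongside; (2) fluorescence yield
# tables constructed by inverting the PSII parameter definitions, so the
# configured efficiencies are recovered exactly at zero noise; (3) pigment
# tables with configured per-PPFD means, a pre/post-recovery zeaxanthin
# conversion that conserves the xanthophyll-cycle pool, and dark Fv/Fm
# values lying on a configured line against Z/(V+A+Z).

#' Scene description for the synthetic dish renderer
#'
#' Defaults describe a 400 x 400 px photograph of a 145-mm inner-diameter
#' crystallizing dish (radius 180 px, so 72.5 mm / 180 px per pixel) on a
#' dark bench, with bluish water and green elliptical fronds. Mother
#' fronds are rendered slightly darker than daughter fronds to stress the
#' color threshold.
#'
#' @param image_width_px,image_height_px Image size in pixels.
#' @param dish_center_px Circle center, (row, col).
#' @param dish_radius_px Water-surface radius in pixels.
#' @param metres_per_px Physical pixel size (m).
#' @param background_color,water_color,frond_color_mean RGB triples in
#'   `[0, 255]`.
#' @param frond_color_sd Per-channel sd of the per-frond color jitter.
#' @param frond_axis_mm_range Range of ellipse semi-axes in mm.
#' @param mother_frond_darkening RGB scaling in `(0, 1]` applied to mother
#'   fronds.
#' @param mother_frond_prob Probability a frond is a (darker) mother frond.
#' @param max_packing_fraction Largest admissible frond coverage of the
#'   water surface; non-overlapping rejection placement saturates well
#'   below 1, so scenarios beyond this are rejected up front.
#' @param seed Integer seed; the renderer is bit-reproducible given the
#'   spec.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_width_px = 400L, image_height_px = 400L,
                       dish_center_px = c(200, 200), dish_radius_px = 180,
                       metres_per_px = 0.0725 / 180,
                       background_color = c(30, 30, 34),
                       water_color = c(70, 110, 165),
                       frond_color_mean = c(70, 150, 60),
                       frond_color_sd = c(8, 8, 8),
                       frond_axis_mm_range = c(1.2, 3.0),
                       mother_frond_darkening = 0.8,
                       mother_frond_prob = 0.3,
                       max_packing_fraction = 0.6,
                       seed = 1L) {
  stopifnot(image_width_px > 0, image_height_px > 0, dish_radius_px > 0,
            metres_per_px > 0,
            dish_center_px[1] - dish_radius_px >= 1,
            dish_center_px[1] + dish_radius_px <= image_height_px,
            dish_center_px[2] - dish_radius_px >= 1,
            dish_center_px[2] + dish_radius_px <= image_width_px,
            all(c(background_color, water_color, frond_color_mean) >= 0),
            all(c(background_color, water_color, frond_color_mean) <= 255),
            all(frond_color_sd >= 0),
            length(frond_axis_mm_range) == 2L,
            frond_axis_mm_range[1] > 0,
            frond_axis_mm_range[1] <= frond_axis_mm_range[2],
            mother_frond_darkening > 0, mother_frond_darkening <= 1,
            mother_frond_prob >= 0, mother_frond_prob <= 1,
            max_packing_fraction > 0, max_packing_fraction <= 1)
  structure(as.list(environment()), class = "scene_spec")
}

#' Growth scenario for the synthetic dish series
#'
#' @param initial_area_m2 Initial total frond area FA0 (m^2).
#' @param rgr_per_day Relative growth rate (day^-1); may be 0 or negative.
#' @param ppfd_umol_m2_s Growth PPFD the dish is assigned to (metadata for
#'   downstream stages).
#' @param duration_days Length of the characterized-growth phase (days).
#' @param imaging_interval_days Days between photographs.
#' @return A `growth_scenario` list.
#' @export
growth_scenario <- function(initial_area_m2, rgr_per_day = 0.2,
                            ppfd_umol_m2_s = 100, duration_days = 4,
                            imaging_interval_days = 1) {
  stopifnot(initial_area_m2 > 0, duration_days > 0,
            imaging_interval_days > 0, ppfd_umol_m2_s >= 0)
  structure(list(initial_area_m2 = initial_area_m2,
                 rgr_per_day = rgr_per_day,
                 ppfd_umol_m2_s = ppfd_umol_m2_s,
                 duration_days = duration_days,
                 imaging_interval_days = imaging_interval_days),
            class = "growth_scenario")
}

# pixel centers inside an ellipse at (center[1], center[2]) with semi-axes
# a, b (px) rotated by theta; returns linear indices into an h x w matrix
raster_ellipse <- function(h, w, center, a, b, theta) {
  r0 <- max(1L, floor(center[1] - max(a, b)))
  r1 <- min(h, ceiling(center[1] + max(a, b)))
  c0 <- max(1L, floor(center[2] - max(a, b)))
  c1 <- min(w, ceiling(center[2] + max(a, b)))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr <- matrix(rows - center[1], length(rows), length(cols))
  dc <- matrix(cols - center[2], length(rows), length(cols), byrow = TRUE)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx_r <- row(inside)[inside] + r0 - 1L
  idx_c <- col(inside)[inside] + c0 - 1L
  idx_r + (idx_c - 1L) * h
}

# Place non-overlapping elliptical fronds inside `water` until exactly
# `target_px` pixels are covered. Returns list(mask, fronds) where fronds
# is a list of per-frond linear index vectors. The last frond is sized to
# close the remaining gap and then trimmed/grown pixel-wise so the total
# count is exact.
place_fronds <- function(h, w, water, target_px, axis_px_range,
                         max_retries = 400L) {
  occupied <- matrix(FALSE, h, w)
  fronds <- list()
  placed <- 0L
  water_idx <- which(water)
  amin <- max(axis_px_range[1], 1)
  amax <- max(axis_px_range[2], amin)
  min_area <- pi * amin^2

  while (placed < target_px) {
    remaining <- target_px - placed
    a <- stats::runif(1, amin, amax)
    b <- stats::runif(1, amin, amax)
    if (pi * a * b > remaining) {  # final frond: close the gap
      s <- sqrt(remaining / (pi * a * b))
      a <- max(a * s, 1); b <- max(b * s, 1)
    }
    theta <- stats::runif(1, 0, pi)
    success <- FALSE
    for (try in seq_len(max_retries)) {
      free_idx <- water_idx[!occupied[water_idx]]
      if (!length(free_idx)) break
      ci <- free_idx[sample.int(length(free_idx), 1L)]
      center <- c((ci - 1L) %% h + 1L, (ci - 1L) %/% h + 1L)
      idx <- raster_ellipse(h, w, center, a, b, theta)
      if (length(idx) && all(water[idx]) && !any(occupied[idx])) {
        occupied[idx] <- TRUE
        fronds[[length(fronds) + 1L]] <- idx
        placed <- placed + length(idx)
        success <- TRUE
        break
      }
      if (try %% 100L == 0L) {  # crowded dish: shrink and keep trying
        a <- max(a * 0.8, 1); b <- max(b * 0.8, 1)
      }
    }
    if (!success)
      stop("could not place a frond after ", max_retries,
           " retries; dish too crowded (", round(placed / sum(water), 2),
           " coverage reached)")
  }

  excess <- placed - target_px
  if (excess > 0L) {  # trim outermost pixels of the last frond
    idx <- fronds[[length(fronds)]]
    if (excess >= length(idx))
      stop("internal error: final frond smaller than trim amount")
    center <- c(mean((idx - 1L) %% h + 1L), mean((idx - 1L) %/% h + 1L))
    d2 <- ((idx - 1L) %% h + 1L - center[1])^2 +
      ((idx - 1L) %/% h + 1L - center[2])^2
    drop_idx <- idx[order(-d2)][seq_len(excess)]
    occupied[drop_idx] <- FALSE
    fronds[[length(fronds)]] <- setdiff(idx, drop_idx)
  }
  list(mask = occupied, fronds = fronds)
}

#' Render a synthetic dish-image time series with exact ground truth
#'
#' For each imaged day `t` the target frond area is
#' `FA0 * exp(RGR * t)`, quantized to whole pixels; non-overlapping
#' elliptical fronds are placed by rejection sampling inside the water
#' circle until the rendered mask covers exactly that many pixels, so the
#' returned `true_area_m2` (mask pixel count x metres_per_px^2) matches
#' the analytic curve to within half a pixel. Scenarios whose final-day
#' area exceeds `max_packing_fraction` of the water surface are rejected.
#' Deterministic given `scene$seed`.
#'
#' @param scene A [scene_spec()].
#' @param growth A [growth_scenario()].
#' @param dish_id Dish label used in the records.
#' @return List of per-day records, each a list with `image`
#'   (H x W x 3, 8-bit RGB), `mask` (H x W logical ground truth), `day`,
#'   `true_area_m2`, `dish_id`; the scene geometry is attached as
#'   attribute `"geometry"` and a manifest data frame as `"manifest"`.
#' @export
generate_dish_series <- function(scene, growth, dish_id = "dish1") {
  stopifnot(inherits(scene, "scene_spec"), inherits(growth, "growth_scenario"))
  h <- scene$image_height_px; w <- scene$image_width_px
  mpp <- scene$metres_per_px
  water <- disc_mask(h, w, scene$dish_center_px, scene$dish_radius_px)
  water_px <- sum(water)
  px_area <- mpp^2
  days <- seq(0, growth$duration_days, by = growth$imaging_interval_days)
  if (days[length(days)] < growth$duration_days)
    days <- c(days, growth$duration_days)
  target_area <- growth$initial_area_m2 * exp(growth$rgr_per_day * days)
  target_px <- as.integer(round(target_area / px_area))
  if (any(target_px < 1L))
    stop("scenario area falls below one pixel; increase initial_area_m2")
  if (max(target_px) > scene$max_packing_fraction * water_px)
    stop("scenario overflow: frond area would reach ",
         round(max(target_px) / water_px, 2), " of the water surface, above ",
         "the max packing fraction ", scene$max_packing_fraction)

  mm_per_px <- mpp * 1000
  axis_px_range <- scene$frond_axis_mm_range / mm_per_px
  axis_colors <- function(n, mother) {
    base <- matrix(scene$frond_color_mean, n, 3L, byrow = TRUE)
    base[mother, ] <- base[mother, , drop = FALSE] * scene$mother_frond_darkening
    jitter <- matrix(stats::rnorm(n * 3L, 0, scene$frond_color_sd), n, 3L,
                     byrow = TRUE)
    pmin(pmax(base + jitter, 0), 255)
  }

  records <- vector("list", length(days))
  for (k in seq_along(days)) {
    # per-day substream so each day is independently reproducible
    set.seed(as.integer((as.numeric(scene$seed) + 7919 * k) %% 2147483647))
    pf <- place_fronds(h, w, water, target_px[k], axis_px_range)
    n_fronds <- length(pf$fronds)
    mother <- stats::runif(n_fronds) < scene$mother_frond_prob
    cols <- axis_colors(n_fronds, mother)
    img <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      plane <- matrix(scene$background_color[ch], h, w)
      plane[water] <- scene$water_color[ch]
      for (f in seq_len(n_fronds)) plane[pf$fronds[[f]]] <- cols[f, ch]
      img[, , ch] <- plane
    }
    records[[k]] <- list(image = round(img), mask = pf$mask, day = days[k],
                         true_area_m2 = target_px[k] * px_area,
                         dish_id = dish_id)
  }
  attr(records, "geometry") <- list(center_px = scene$dish_center_px,
                                    radius_px = scene$dish_radius_px,
                                    metres_per_px = mpp)
  attr(records, "manifest") <- data.frame(
    dish_id = dish_id, day = days, true_area_m2 = target_px * px_area,
    seed = scene$seed, stringsAsFactors = FALSE)
  records
}

#' Convert a generated dish record to a [dish_image()]
#'
#' @param record One element of a [generate_dish_series()] result.
#' @param geometry Geometry to attach (typically the series'
#'   `"geometry"` attribute).
#' @return A [dish_image()].
#' @export
as_dish_image <- function(record, geometry = NULL) {
  dish_image(record$image, dish_id = record$dish_id, day = record$day,
             geometry = geometry)
}

#' Fluorescence-table scenario
#'
#' Per growth PPFD, the true light-adapted efficiency of open PSII centers
#' (Fv'/Fm') and the true fraction of closed centers (1 - qP), plus dark
#' Fv/Fm before and after low-light recovery. Defaults follow the
#' qualitative pattern seen in high-light acclimation: Fv'/Fm' declines
#' and 1 - qP rises with growth PPFD; dark Fv/Fm dips slightly before
#' recovery and rebounds to a common high value after.
#'
#' @param ppfd Growth PPFDs (one scenario row per level).
#' @param true_FvpFmp,true_oneMinusQP Per-PPFD true values, recycled to
#'   `length(ppfd)`; efficiencies in `[0, max_efficiency]`, fractions in
#'   `[0, 1]`.
#' @param fvfm_dark_pre,fvfm_dark_post Dark Fv/Fm immediately on removal
#'   from growth light and after recovery.
#' @param noise_sd Multiplicative Gaussian noise sd applied to every
#'   emitted yield (clipped to stay positive); 0 gives exact round-trips.
#' @param max_efficiency Upper bound for `true_FvpFmp`.
#' @param seed Integer seed.
#' @return A `fluor_scenario` list.
#' @export
fluor_scenario <- function(ppfd = c(100, 200, 500, 700),
                           true_FvpFmp = c(0.72, 0.62, 0.45, 0.38),
                           true_oneMinusQP = c(0.15, 0.30, 0.55, 0.58),
                           fvfm_dark_pre = c(0.82, 0.80, 0.77, 0.74),
                           fvfm_dark_post = c(0.83, 0.83, 0.82, 0.81),
                           noise_sd = 0, max_efficiency = 0.8, seed = 1L) {
  n <- length(ppfd)
  true_FvpFmp <- rep_len(true_FvpFmp, n)
  true_oneMinusQP <- rep_len(true_oneMinusQP, n)
  fvfm_dark_pre <- rep_len(fvfm_dark_pre, n)
  fvfm_dark_post <- rep_len(fvfm_dark_post, n)
  if (any(true_FvpFmp > max_efficiency))
    stop("true_FvpFmp exceeds max_efficiency (", max_efficiency, ")")
  stopifnot(all(true_FvpFmp >= 0), all(true_oneMinusQP >= 0),
            all(true_oneMinusQP <= 1),
            all(fvfm_dark_pre > 0), all(fvfm_dark_pre < 1),
            all(fvfm_dark_post > 0), all(fvfm_dark_post < 1),
            noise_sd >= 0)
  structure(list(ppfd = ppfd, true_FvpFmp = true_FvpFmp,
                 true_oneMinusQP = true_oneMinusQP,
                 fvfm_dark_pre = fvfm_dark_pre,
                 fvfm_dark_post = fvfm_dark_post,
                 noise_sd = noise_sd, max_efficiency = max_efficiency,
                 seed = seed),
            class = "fluor_scenario")
}

# multiplicative Gaussian noise, clipped so yields stay positive
.mnoise <- function(x, sd) {
  if (sd == 0) return(x)
  x * pmax(1 + stats::rnorm(length(x), 0, sd), 1e-3)
}

#' Generate a fluorescence yield table by inverting the PSII definitions
#'
#' Yields are constructed so that at zero noise [derive_psii()] returns the
#' scenario's true values exactly: with an arbitrary yield scale
#' `Fm' = 2`, `Fo' = Fm' (1 - Fv'/Fm')` and
#' `F = Fo' + (1 - qP)(Fm' - Fo')`; dark rows use `Fm = 2.5`,
#' `Fo = Fm (1 - Fv/Fm)`. Three rows per dish are emitted: `light`,
#' `dark_pre` (immediately off the growth light) and `dark_post` (after
#' low-light recovery).
#'
#' @param scn A [fluor_scenario()].
#' @param dishes_per_ppfd Number of replicate dishes per PPFD (>= 1).
#' @return Data frame with columns `dish_id`, `growth_ppfd`, `state`,
#'   `Fo`, `Fm`, `F`, `Fmp`, `Fop` (NA where a yield does not exist in
#'   that state).
#' @export
generate_fluorescence_table <- function(scn, dishes_per_ppfd = 3L) {
  stopifnot(inherits(scn, "fluor_scenario"), dishes_per_ppfd >= 1L)
  set.seed(scn$seed)
  Fmp0 <- 2.0; Fm0 <- 2.5
  rows <- list()
  for (i in seq_along(scn$ppfd)) {
    for (d in seq_len(dishes_per_ppfd)) {
      id <- sprintf("p%d_d%d", scn$ppfd[i], d)
      Fop <- Fmp0 * (1 - scn$true_FvpFmp[i])
      F <- Fop + scn$true_oneMinusQP[i] * (Fmp0 - Fop)
      # light-state F coincides with Fo' when all centers are open; keep
      # the degenerate zero-efficiency row (Fm' = Fo' = F) so downstream
      # code must flag it rather than crash
      light <- data.frame(dish_id = id, growth_ppfd = scn$ppfd[i],
                          state = "light", Fo = NA_real_, Fm = NA_real_,
                          F = .mnoise(F, scn$noise_sd),
                          Fmp = .mnoise(Fmp0, scn$noise_sd),
                          Fop = .mnoise(Fop, scn$noise_sd),
                          stringsAsFactors = FALSE)
      dark <- function(state, fvfm) data.frame(
        dish_id = id, growth_ppfd = scn$ppfd[i], state = state,
        Fo = .mnoise(Fm0 * (1 - fvfm), scn$noise_sd),
        Fm = .mnoise(Fm0, scn$noise_sd),
        F = NA_real_, Fmp = NA_real_, Fop = NA_real_,
        stringsAsFactors = FALSE)
      rows <- c(rows, list(light, dark("dark_pre", scn$fvfm_dark_pre[i]),
                           dark("dark_post", scn$fvfm_dark_post[i])))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pigment-table scenario
#'
#' Per-PPFD mean concentrations (per frond area, arbitrary but consistent
#' units) for the eight quantified pigments, within-dish noise, the
#' fraction of zeaxanthin reconverted to violaxanthin during the 30-min
#' low-light recovery, and a linear relation tying dark Fv/Fm to the
#' zeaxanthin fraction of the xanthophyll-cycle pool. Default trends are
#' monotone in PPFD: chlorophyll falls, the V+A+Z pool and zeaxanthin
#' rise (zeaxanthin from negligible at the lowest PPFD).
#'
#' @param ppfd Growth PPFDs.
#' @param means Matrix (length(ppfd) x 8) of mean concentrations, columns
#'   `chl_a`, `chl_b`, `viola`, `anthera`, `zea`, `lutein`, `beta_car`,
#'   `neo`; all non-negative.
#' @param within_sd Relative (multiplicative) within-dish noise sd.
#' @param zea_recovery_removal Fraction of pre-recovery zeaxanthin
#'   converted back to violaxanthin in the post sample (pool-conserving).
#' @param fvfm_slope,fvfm_intercept Dark Fv/Fm = intercept + slope x
#'   Z/(V+A+Z).
#' @param seed Integer seed.
#' @return A `pigment_scenario` list.
#' @export
pigment_scenario <- function(ppfd = c(100, 200, 500, 700),
                             means = default_pigment_means(ppfd),
                             within_sd = 0,
                             zea_recovery_removal = 0.5,
                             fvfm_slope = -0.3, fvfm_intercept = 0.84,
                             seed = 1L) {
  means <- as.matrix(means)
  stopifnot(nrow(means) == length(ppfd), ncol(means) == 8L,
            all(is.finite(means)), all(means >= 0),
            within_sd >= 0, zea_recovery_removal >= 0,
            zea_recovery_removal <= 1, is.finite(fvfm_slope))
  colnames(means) <- .pigment_cols
  structure(list(ppfd = ppfd, means = means, within_sd = within_sd,
                 zea_recovery_removal = zea_recovery_removal,
                 fvfm_slope = fvfm_slope, fvfm_intercept = fvfm_intercept,
                 seed = seed),
            class = "pigment_scenario")
}

#' Default per-PPFD pigment means
#'
#' Smooth monotone trends (concentration per frond area, arbitrary
#' consistent units) qualitatively matching high-light acclimation:
#' chlorophylls decline above 200 umol m^-2 s^-1, the xanthophyll-cycle
#' pool grows, zeaxanthin rises from near zero at the lowest PPFD to
#' about a third of the pool at the highest, lutein and beta-carotene
#' decline modestly.
#'
#' @param ppfd Growth PPFDs.
#' @return Matrix with one row per PPFD and the eight pigment columns.
#' @export
default_pigment_means <- function(ppfd = c(100, 200, 500, 700)) {
  f <- (ppfd - min(ppfd)) / max(max(ppfd) - min(ppfd), 1)  # 0..1
  vaz <- 30 + 50 * f
  zfrac <- 0.35 * f          # Z as a fraction of the pool
  cbind(chl_a = 330 - 90 * f, chl_b = 110 - 30 * f,
        viola = vaz * (1 - zfrac) * 0.85, anthera = vaz * (1 - zfrac) * 0.15,
        zea = vaz * zfrac,
        lutein = 60 - 12 * f, beta_car = 35 - 7 * f, neo = 12 - 2 * f)
}

#' Generate a pigment concentration table with co-generated dark Fv/Fm
#'
#' Emits one pre-recovery and one post-recovery sample per dish. The
#' post-recovery sample converts `zea_recovery_removal` of the zeaxanthin
#' back to violaxanthin, conserving the V+A+Z pool. A `dark_fvfm` column
#' is co-generated from each sample's Z/(V+A+Z) via the scenario's linear
#' relation, so a regression of dark Fv/Fm on the zeaxanthin fraction
#' recovers the configured slope and intercept exactly at zero noise.
#'
#' @param scn A [pigment_scenario()].
#' @param dishes_per_ppfd Replicate dishes per PPFD.
#' @param samples_per_dish Samples per dish; must be 2 (the pre/post
#'   recovery pair).
#' @param frond_area_m2 Nominal frond area of each ~10-frond sample.
#' @return Data frame with `dish_id`, `growth_ppfd`, `recovery`, the
#'   eight pigment columns, `frond_area_m2` and `dark_fvfm`.
#' @export
generate_pigment_table <- function(scn, dishes_per_ppfd = 3L,
                                   samples_per_dish = 2L,
                                   frond_area_m2 = 1e-4) {
  stopifnot(inherits(scn, "pigment_scenario"), dishes_per_ppfd >= 1L)
  if (samples_per_dish != 2L)
    stop("exactly two samples per dish are supported: ",
         "one pre- and one post-recovery")
  set.seed(scn$seed)
  rows <- list()
  for (i in seq_along(scn$ppfd)) {
    for (d in seq_len(dishes_per_ppfd)) {
      id <- sprintf("p%d_d%d", scn$ppfd[i], d)
      conc <- .mnoise(scn$means[i, ], scn$within_sd)
      pre <- as.list(conc)
      post <- pre
      moved <- pre$zea * scn$zea_recovery_removal
      post$zea <- pre$zea - moved
      post$viola <- pre$viola + moved
      emit <- function(recovery, s) {
        vaz <- s$viola + s$anthera + s$zea
        zf <- if (vaz > 0) s$zea / vaz else 0
        data.frame(dish_id = id, growth_ppfd = scn$ppfd[i],
                   recovery = recovery, as.data.frame(s),
                   frond_area_m2 = frond_area_m2,
                   dark_fvfm = scn$fvfm_intercept + scn$fvfm_slope * zf,
                   stringsAsFactors = FALSE)
      }
      rows <- c(rows, list(emit("pre", pre), emit("post", post)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
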