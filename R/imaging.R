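# Frond-area measurement from top-down dish photographs.
#
# The measurement mirrors the classical two-step procedure: (1) mask the
# water surface inside the crystallizing dish (a circle of known geometry,
# or auto-detected), (2) select green frond pixels inside the mask with an
# HSV color threshold. Frond area = coverage fraction x known water
# surface area. Images are H x W x 3 arrays of 8-bit RGB; coordinates are
# (row, col) with origin top-left; areas are m^2.

#' Construct a dish image object
#'
#' @param pixels `H x W x 3` numeric array, 8-bit RGB in `[0, 255]`.
#' @param dish_id Dish label.
#' @param day Days since the start of the experiment.
#' @param geometry Optional list with `center_px` (row, col), `radius_px`
#'   and `metres_per_px` describing the water-surface circle.
#' @return A `dish_image` object.
#' @export
dish_image <- function(pixels, dish_id = "dish", day = 0, geometry = NULL) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            all(dim(pixels)[1:2] > 0))
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  if (!is.null(geometry))
    stopifnot(length(geometry$center_px) == 2L, geometry$radius_px > 0,
              geometry$metres_per_px > 0)
  structure(list(pixels = pixels, dish_id = as.character(dish_id),
                 day = day, geometry = geometry),
            class = "dish_image")
}

#' @export
print.dish_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("dish_image: %s day %g (%d x %d px%s)\n", x$dish_id, x$day,
              d[1], d[2],
              if (is.null(x$geometry)) "" else ", geometry attached"))
  invisible(x)
}

# logical disc: pixel centers within radius of (center row, center col)
disc_mask <- function(h, w, center, radius) {
  dr <- matrix(seq_len(h) - center[1L], h, w)
  dc <- matrix(seq_len(w) - center[2L], h, w, byrow = TRUE)
  dr * dr + dc * dc <= radius * radius
}

#' Mask the water surface inside the dish
#'
#' In config mode (the default whenever geometry is available) the mask is
#' the exact circle given by `center_px`/`radius_px`, and
#' `water_area_m2 = pi (radius_px x metres_per_px)^2`. In auto mode the
#' dish interior is found as the connected blob of pixels whose color
#' differs from the background (estimated from the image border); its
#' centroid and equivalent-area radius define the circle, which must be
#' plausibly circular.
#'
#' @param img A [dish_image()].
#' @param geometry Geometry list (see [dish_image()]); defaults to the
#'   geometry attached to the image. `NULL` triggers auto-detection.
#' @param metres_per_px Required in auto mode (scale cannot be inferred
#'   from pixels alone).
#' @param color_tol Auto mode: minimal per-channel deviation from the
#'   background color for a pixel to count as dish interior.
#' @return A `water_mask` object: list with `mask` (H x W logical),
#'   `water_area_m2`, `center_px`, `radius_px`, `metres_per_px`, `source`
#'   (`"config"` or `"detected"`).
#' @export
detect_water_mask <- function(img, geometry = img$geometry,
                              metres_per_px = NULL, color_tol = 40) {
  stopifnot(inherits(img, "dish_image"))
  d <- dim(img$pixels)
  if (!is.null(geometry)) {
    mask <- disc_mask(d[1], d[2], geometry$center_px, geometry$radius_px)
    mpp <- geometry$metres_per_px
    center <- geometry$center_px
    radius <- geometry$radius_px
    source <- "config"
  } else {
    if (is.null(metres_per_px))
      stop("auto water-mask detection needs metres_per_px")
    mpp <- metres_per_px
    border <- rbind(matrix(img$pixels[1, , ], ncol = 3L),
                    matrix(img$pixels[d[1], , ], ncol = 3L),
                    matrix(img$pixels[, 1, ], ncol = 3L),
                    matrix(img$pixels[, d[2], ], ncol = 3L))
    bg <- apply(border, 2L, stats::median)
    dev <- pmax(abs(img$pixels[, , 1] - bg[1]),
                abs(img$pixels[, , 2] - bg[2]),
                abs(img$pixels[, , 3] - bg[3]))
    interior <- dev > color_tol
    npx <- sum(interior)
    if (npx < 50)
      stop("no dish found in image of dish '", img$dish_id,
           "' (day ", img$day, "): too few non-background pixels")
    rows <- row(interior)[interior]; cols <- col(interior)[interior]
    center <- c(mean(rows), mean(cols))
    radius <- sqrt(npx / pi)
    mask <- disc_mask(d[1], d[2], center, radius)
    # plausibility: the flagged pixels should fill the fitted circle
    fill <- sum(interior & mask) / sum(mask)
    if (fill < 0.9)
      stop("detected region in image of dish '", img$dish_id,
           "' is not circular (fill fraction ", round(fill, 2), ")")
    source <- "detected"
  }
  if (!any(mask)) stop("water mask is empty")
  structure(list(mask = mask, water_area_m2 = pi * (radius * mpp)^2,
                 center_px = center, radius_px = radius,
                 metres_per_px = mpp, source = source),
            class = "water_mask")
}

#' Color-threshold configuration for frond segmentation
#'
#' Fronds are selected in HSV space: hue inside a green window, with
#' minimum saturation and value to reject water and background. Hue is on
#' the `[0, 1]` circle (green ~ 1/3, as returned by
#' [grDevices::rgb2hsv()]). Defaults are calibrated against the synthetic
#' dish generator.
#'
#' @param hue_range Length-2 numeric, lower/upper hue bound.
#' @param min_saturation,min_value Minimal S and V in `[0, 1]`.
#' @param min_blob_px Remove connected frond components smaller than this
#'   many pixels (0 = keep everything, the default: faithful to the bare
#'   threshold definition).
#' @return A `frond_thresholds` list.
#' @export
frond_thresholds <- function(hue_range = c(0.16, 0.50), min_saturation = 0.20,
                             min_value = 0.10, min_blob_px = 0L) {
  stopifnot(length(hue_range) == 2L, hue_range[1] < hue_range[2],
            min_saturation >= 0, min_saturation <= 1,
            min_value >= 0, min_value <= 1, min_blob_px >= 0)
  structure(list(hue_range = hue_range, min_saturation = min_saturation,
                 min_value = min_value, min_blob_px = as.integer(min_blob_px)),
            class = "frond_thresholds")
}

# 4-connected component labelling by repeated label propagation;
# adequate for the small masks seen here
remove_small_blobs <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    old <- lab
    shifted <- function(dr, dc) {
      out <- matrix(0L, h, w)
      rs <- max(1, 1 + dr):min(h, h + dr)
      cs <- max(1, 1 + dc):min(w, w + dc)
      out[rs, cs] <- lab[rs - dr, cs - dc]
      out
    }
    for (s in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      nb <- shifted(s[1], s[2])
      upd <- mask & nb > 0L & (lab == 0L | nb < lab)
      lab[upd] <- nb[upd]
    }
    if (identical(lab, old)) break
  }
  sizes <- table(lab[mask])
  small <- as.integer(names(sizes)[sizes < min_px])
  mask[lab %in% small] <- FALSE
  mask
}

#' Threshold green frond pixels inside the water mask
#'
#' @param img A [dish_image()].
#' @param water A `water_mask` from [detect_water_mask()].
#' @param thresholds A [frond_thresholds()] configuration.
#' @return H x W logical frond mask (a subset of the water mask). An empty
#'   mask is a valid result.
#' @export
threshold_fronds <- function(img, water, thresholds = frond_thresholds()) {
  stopifnot(inherits(img, "dish_image"), inherits(water, "water_mask"),
            inherits(thresholds, "frond_thresholds"),
            identical(dim(img$pixels)[1:2], dim(water$mask)))
  px <- matrix(img$pixels, ncol = 3L)
  hsv <- grDevices::rgb2hsv(t(px), maxColorValue = 255)
  keep <- hsv[1L, ] >= thresholds$hue_range[1] &
    hsv[1L, ] <= thresholds$hue_range[2] &
    hsv[2L, ] >= thresholds$min_saturation &
    hsv[3L, ] >= thresholds$min_value
  mask <- matrix(keep, nrow(water$mask), ncol(water$mask)) & water$mask
  if (thresholds$min_blob_px > 0L)
    mask <- remove_small_blobs(mask, thresholds$min_blob_px)
  mask
}

#' Measure frond area of one dish image
#'
#' Coverage fraction = frond pixels / water pixels; frond area = coverage
#' fraction x water surface area.
#'
#' @inheritParams threshold_fronds
#' @return One-row data frame (`dish_id`, `day`, `coverage_fraction`,
#'   `frond_area_m2`).
#' @export
measure_frond_area <- function(img, water, thresholds = frond_thresholds()) {
  fronds <- threshold_fronds(img, water, thresholds)
  coverage <- sum(fronds) / sum(water$mask)
  data.frame(dish_id = img$dish_id, day = img$day,
             coverage_fraction = coverage,
             frond_area_m2 = coverage * water$water_area_m2,
             stringsAsFactors = FALSE)
}

#' Measure frond areas for a directory or list of images
#'
#' @param images A list of [dish_image()] objects, or a character vector
#'   of PNG paths (read with [read_dish_image()]; dish id and day are then
#'   parsed from `<dish_id>_day<d>.png` filenames).
#' @param geometry Shared dish geometry (see [dish_image()]); per-image
#'   geometry wins if attached.
#' @param thresholds A [frond_thresholds()] configuration.
#' @return Data frame of frond-area records, one row per image.
#' @export
measure_frond_areas <- function(images, geometry = NULL,
                                thresholds = frond_thresholds()) {
  if (is.character(images))
    images <- lapply(images, read_dish_image, geometry = geometry)
  rows <- lapply(images, function(img) {
    water <- detect_water_mask(img, geometry = if (is.null(img$geometry))
      geometry else img$geometry)
    measure_frond_area(img, water, thresholds)
  })
  do.call(rbind, rows)
}

#' Read a dish photograph from a PNG file
#'
#' @param path PNG file path; when `dish_id`/`day` are missing they are
#'   parsed from a `<dish_id>_day<d>.png` basename.
#' @param dish_id,day Overrides for the parsed values.
#' @param geometry Optional geometry to attach.
#' @return A [dish_image()].
#' @export
read_dish_image <- function(path, dish_id = NULL, day = NULL, geometry = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px <- px[, , 1:3, drop = FALSE] * 255
  base <- sub("\\.png$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(base, regexec("^(.*)_day([0-9.]+)$", base))[[1L]]
  if (is.null(dish_id)) dish_id <- if (length(m)) m[2L] else base
  if (is.null(day)) day <- if (length(m)) as.numeric(m[3L]) else 0
  dish_image(px, dish_id = dish_id, day = day, geometry = geometry)
}

#' Write a dish image (and optionally its ground-truth mask) as PNG
#'
#' @param img A [dish_image()] or a record from [generate_dish_series()].
#' @param path Output PNG path.
#' @param mask_path Optional path for the binary ground-truth mask.
#' @return `path`, invisibly.
#' @export
write_dish_image <- function(img, path, mask_path = NULL) {
  px <- if (inherits(img, "dish_image")) img$pixels else img$image
  png::writePNG(px / 255, path)
  if (!is.null(mask_path) && !is.null(img$mask))
    png::writePNG(img$mask * 1, mask_path)
  invisible(path)
}
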