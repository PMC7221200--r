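# End-to-end orchestration: simulate -> segment -> growth -> fluorescence
# -> pigments -> stats, sharing one config, with a manifest written last.
# All stage outputs are plain CSV (comma-separated, UTF-8, header row,
# "." decimal) so any stage can also be run standalone.

#' Build a run configuration
#'
#' @param ppfd Growth PPFDs; one treatment group per level. Defaults to
#'   the four-level design 100/200/500/700 umol m^-2 s^-1.
#' @param dishes_per_ppfd Replicate dishes per PPFD (3 by default).
#' @param t4 Length of the characterized-growth phase in days.
#' @param imaging_interval_days Days between photographs.
#' @param initial_area_m2 Initial frond area per dish (roughly 20 fronds).
#' @param rgr_by_ppfd Named numeric: true RGR per PPFD level used by the
#'   simulate stage; defaults to a mild increase with PPFD.
#' @param scene A [scene_spec()] providing dish geometry and rendering
#'   parameters (its seed is overridden per dish from `seed`).
#' @param thresholds A [frond_thresholds()] configuration.
#' @param max_efficiency,alpha Passed to the fluorescence and stats
#'   stages.
#' @param seed Master seed; per-dish and per-table seeds are derived from
#'   it.
#' @param out_dir Output directory for all stage files.
#' @return A `run_config` list.
#' @export
run_config <- function(ppfd = c(100, 200, 500, 700), dishes_per_ppfd = 3L,
                       t4 = 4, imaging_interval_days = 1,
                       initial_area_m2 = 2e-4,
                       rgr_by_ppfd = NULL,
                       scene = scene_spec(),
                       thresholds = frond_thresholds(),
                       max_efficiency = 0.8, alpha = 0.05,
                       seed = 1L, out_dir = tempfile("lemnaquant_run_")) {
  stopifnot(length(ppfd) >= 1L, all(ppfd > 0), dishes_per_ppfd >= 1L,
            t4 > 0, imaging_interval_days > 0, initial_area_m2 > 0,
            inherits(scene, "scene_spec"),
            inherits(thresholds, "frond_thresholds"),
            max_efficiency > 0, alpha > 0, alpha < 1)
  if (is.null(rgr_by_ppfd)) {
    # RGR rises modestly with PPFD (about +25% from lowest to highest)
    f <- (ppfd - min(ppfd)) / max(max(ppfd) - min(ppfd), 1)
    rgr_by_ppfd <- stats::setNames(0.20 + 0.05 * f, as.character(ppfd))
  }
  stopifnot(all(as.character(ppfd) %in% names(rgr_by_ppfd)))
  structure(list(ppfd = ppfd, dishes_per_ppfd = as.integer(dishes_per_ppfd),
                 t4 = t4, imaging_interval_days = imaging_interval_days,
                 initial_area_m2 = initial_area_m2,
                 rgr_by_ppfd = rgr_by_ppfd, scene = scene,
                 thresholds = thresholds, max_efficiency = max_efficiency,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# stable hash of the config (md5 of its serialization)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2L)
  unname(tools::md5sum(tmp))
}

.dish_ids <- function(config) {
  unlist(lapply(config$ppfd, function(p)
    sprintf("p%d_d%d", p, seq_len(config$dishes_per_ppfd))))
}

.ppfd_of_dish <- function(config) {
  stats::setNames(rep(config$ppfd, each = config$dishes_per_ppfd),
                  .dish_ids(config))
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order inside `config$out_dir`:
#' `simulate` (dish PNGs + ground-truth manifest, fluorescence and
#' pigment tables), `segment` (`areas.csv`), `growth` (`growth.csv`),
#' `fluorescence` (`psii.csv`), `pigments` (`pigments.csv`) and `stats`
#' (`stats.csv` with Tukey-Kramer letters for RGR, light-use efficiency
#' and pigment pools by PPFD). Identical config and seed reproduce
#' byte-identical CSVs. The manifest (`manifest.json` when jsonlite is
#' available, else `manifest.csv` of stage/file/rows) is written last.
#'
#' @param config A [run_config()].
#' @param keep_images Write the simulated PNGs (default `TRUE`; the
#'   segment stage then reads them back from disk, exercising the image
#'   I/O path).
#' @return The run manifest, invisibly: list with `config_hash`,
#'   `package_version`, `stages` (per-stage files and row counts) and
#'   `warnings`.
#' @export
run_all <- function(config, keep_images = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stages <- list()
  warns <- character(0)
  note_stage <- function(name, files, rows) {
    stages[[name]] <<- list(files = files, rows = rows)
    message("[", name, "] ", paste(basename(files), collapse = ", "),
            " (", rows, " rows)")
  }

  ## simulate ---------------------------------------------------------
  ids <- .dish_ids(config)
  ppfd_of <- .ppfd_of_dish(config)
  img_dir <- out("images")
  if (keep_images) dir.create(img_dir, showWarnings = FALSE)
  images <- list()
  truth <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    scene <- config$scene
    scene$seed <- (config$seed + 1009L * i) %% 2147483647L
    growth <- growth_scenario(config$initial_area_m2,
                              rgr_per_day = config$rgr_by_ppfd[[as.character(ppfd_of[[id]])]],
                              ppfd_umol_m2_s = ppfd_of[[id]],
                              duration_days = config$t4,
                              imaging_interval_days = config$imaging_interval_days)
    series <- generate_dish_series(scene, growth, dish_id = id)
    geom <- attr(series, "geometry")
    truth[[id]] <- attr(series, "manifest")
    for (rec in series) {
      img <- as_dish_image(rec, geometry = geom)
      if (keep_images) {
        path <- file.path(img_dir, sprintf("%s_day%g.png", id, rec$day))
        write_dish_image(rec, path)
      }
      images[[length(images) + 1L]] <- img
    }
  }
  truth <- do.call(rbind, truth)
  utils::write.csv(truth, out("truth.csv"), row.names = FALSE)
  fl_scn <- fluor_scenario(ppfd = config$ppfd,
                           max_efficiency = config$max_efficiency,
                           seed = config$seed + 2L)
  fluor <- generate_fluorescence_table(fl_scn, config$dishes_per_ppfd)
  utils::write.csv(fluor, out("fluor_raw.csv"), row.names = FALSE)
  pg_scn <- pigment_scenario(ppfd = config$ppfd, seed = config$seed + 3L)
  pigments_raw <- generate_pigment_table(pg_scn, config$dishes_per_ppfd)
  utils::write.csv(pigments_raw, out("pigments_raw.csv"), row.names = FALSE)
  note_stage("simulate",
             c(out("truth.csv"), out("fluor_raw.csv"), out("pigments_raw.csv")),
             nrow(truth) + nrow(fluor) + nrow(pigments_raw))

  ## segment ----------------------------------------------------------
  if (keep_images) {
    geom <- list(center_px = config$scene$dish_center_px,
                 radius_px = config$scene$dish_radius_px,
                 metres_per_px = config$scene$metres_per_px)
    paths <- list.files(img_dir, pattern = "\\.png$", full.names = TRUE)
    areas <- measure_frond_areas(paths, geometry = geom,
                                 thresholds = config$thresholds)
  } else {
    areas <- measure_frond_areas(images, thresholds = config$thresholds)
  }
  areas <- areas[order(areas$dish_id, areas$day), ]
  utils::write.csv(areas, out("areas.csv"), row.names = FALSE)
  note_stage("segment", out("areas.csv"), nrow(areas))

  ## growth -----------------------------------------------------------
  growth_df <- growth_table(areas, ppfd_of)
  utils::write.csv(growth_df, out("growth.csv"), row.names = FALSE)
  note_stage("growth", out("growth.csv"), nrow(growth_df))

  ## fluorescence -----------------------------------------------------
  psii <- withCallingHandlers(
    psii_table(fluor, max_efficiency = config$max_efficiency),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  utils::write.csv(psii, out("psii.csv"), row.names = FALSE)
  note_stage("fluorescence", out("psii.csv"), nrow(psii))

  ## pigments ---------------------------------------------------------
  pig_sum <- summarize_pigments(pigments_raw)
  pig_sum <- cbind(pig_sum, per_chlorophyll(pig_sum)[
    c("vaz_per_chl", "total_car_per_chl", "zea_per_chl")])
  utils::write.csv(pig_sum, out("pigments.csv"), row.names = FALSE)
  note_stage("pigments", out("pigments.csv"), nrow(pig_sum))

  ## stats ------------------------------------------------------------
  growth_df$ppfd <- factor(growth_df$ppfd)
  pig_sum$growth_ppfd <- factor(pig_sum$growth_ppfd)
  psii$growth_ppfd <- factor(psii$growth_ppfd)
  stat_specs <- list(
    c("growth", "RGR"), c("growth", "lue_m2_per_mol"),
    c("psii", "FvpFmp"), c("psii", "D"),
    c("pigments", "chl_ab"), c("pigments", "vaz"), c("pigments", "zea"))
  tables <- list(growth = growth_df, psii = psii, pigments = pig_sum)
  group_cols <- c(growth = "ppfd", psii = "growth_ppfd",
                  pigments = "growth_ppfd")
  stats_rows <- lapply(stat_specs, function(sp) {
    tab <- group_letters(tables[[sp[1]]], sp[2], group_cols[[sp[1]]],
                         alpha = config$alpha)
    cbind(variable = sp[2], tab, stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, stats_rows)
  utils::write.csv(stats_df, out("stats.csv"), row.names = FALSE)
  note_stage("stats", out("stats.csv"), nrow(stats_df))

  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("lemnaquant")),
                   seed = config$seed,
                   stages = stages, warnings = warns)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
  } else {
    mf <- do.call(rbind, lapply(names(stages), function(nm) data.frame(
      stage = nm, files = paste(basename(stages[[nm]]$files), collapse = ";"),
      rows = stages[[nm]]$rows)))
    utils::write.csv(mf, out("manifest.csv"), row.names = FALSE)
  }
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands. Invoke from a shell as
#' `Rscript -e 'lemnaquant::lemna_cli()' <subcommand> [options]` or via
#' the wrapper script in `system.file("cli", "lemnaquant.R",
#' package = "lemnaquant")`. Subcommands:
#' \describe{
#'   \item{run-all / simulate}{Full synthetic pipeline into `--out-dir`.}
#'   \item{segment}{`--images DIR` of `<dish>_day<d>.png` files to
#'     `areas.csv` (default geometry of [scene_spec()]).}
#'   \item{growth}{`--areas areas.csv` + `--ppfd P` to `growth.csv`.}
#'   \item{fluorescence}{`--table fluor.csv` to `psii.csv`.}
#'   \item{pigments}{`--table pigments_raw.csv` to `pigments.csv`.}
#'   \item{stats}{`--table x.csv --value COL --group COL` to `stats.csv`.}
#' }
#'
#' @param args Character vector of CLI arguments (defaults to the
#'   process's trailing command-line arguments).
#' @return Invisibly, the result of the dispatched stage.
#' @export
lemna_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    stop("usage: lemnaquant <run-all|segment|growth|fluorescence|pigments|stats> [options]",
         call. = FALSE)
  cmd <- args[1L]
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", dest = "out_dir", type = "character",
                          default = "lemnaquant_out"),
    optparse::make_option("--images", type = "character", default = NULL),
    optparse::make_option("--table", type = "character", default = NULL),
    optparse::make_option("--areas", type = "character", default = NULL),
    optparse::make_option("--ppfd", type = "double", default = NA),
    optparse::make_option("--value", type = "character", default = NULL),
    optparse::make_option("--group", type = "character", default = "growth_ppfd"),
    optparse::make_option("--max-efficiency", dest = "max_efficiency",
                          type = "double", default = 0.8),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--out", type = "character", default = NULL))),
    args = args[-1L])
  dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
  dest <- function(default) if (is.null(opts$out))
    file.path(opts$out_dir, default) else opts$out
  need <- function(what, flag) {
    if (is.null(what) || (length(what) == 1L && is.na(what)))
      stop("subcommand '", cmd, "' requires ", flag, call. = FALSE)
    what
  }

  result <- switch(
    cmd,
    "run-all" = , "simulate" = run_all(run_config(
      seed = opts$seed, out_dir = opts$out_dir,
      max_efficiency = opts$max_efficiency, alpha = opts$alpha)),
    "segment" = {
      paths <- list.files(need(opts$images, "--images"),
                          pattern = "\\.png$", full.names = TRUE)
      sc <- scene_spec()
      areas <- measure_frond_areas(paths, geometry = list(
        center_px = sc$dish_center_px, radius_px = sc$dish_radius_px,
        metres_per_px = sc$metres_per_px))
      utils::write.csv(areas, dest("areas.csv"), row.names = FALSE)
      areas
    },
    "growth" = {
      areas <- utils::read.csv(need(opts$areas, "--areas"))
      ppfd <- need(opts$ppfd, "--ppfd")
      gt <- growth_table(areas, stats::setNames(
        rep(ppfd, length(unique(areas$dish_id))), unique(areas$dish_id)))
      utils::write.csv(gt, dest("growth.csv"), row.names = FALSE)
      gt
    },
    "fluorescence" = {
      fl <- utils::read.csv(need(opts$table, "--table"))
      ps <- psii_table(fl, max_efficiency = opts$max_efficiency)
      utils::write.csv(ps, dest("psii.csv"), row.names = FALSE)
      ps
    },
    "pigments" = {
      pg <- summarize_pigments(utils::read.csv(need(opts$table, "--table")))
      utils::write.csv(pg, dest("pigments.csv"), row.names = FALSE)
      pg
    },
    "stats" = {
      tab <- utils::read.csv(need(opts$table, "--table"))
      gl <- group_letters(tab, need(opts$value, "--value"), opts$group,
                          alpha = opts$alpha)
      utils::write.csv(gl, dest("stats.csv"), row.names = FALSE)
      gl
    },
    stop("unknown subcommand: ", cmd, call. = FALSE))
  invisible(result)
}
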