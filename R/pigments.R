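# Pigment-pool arithmetic for the eight HPLC-quantified pigments:
# chlorophylls a and b, violaxanthin (V), antheraxanthin (A), zeaxanthin
# (Z), lutein, beta-carotene and neoxanthin, all expressed per frond area
# in whatever (consistent) unit the input table declares.
#
# Reporting convention: each dish contributes one sample taken immediately
# on removal from the growth light ("pre") and one after ~30 min of
# low-light recovery ("post"). Pigments whose concentration is stable over
# that half hour — the chlorophylls, lutein, beta-carotene, the summed
# xanthophyll-cycle pool V+A+Z and total carotenoids — are reported as the
# mean of the pre and post samples. Zeaxanthin itself interconverts with
# violaxanthin during recovery and is therefore kept separate per recovery
# state, with the pre-recovery value as the headline number.

.pigment_cols <- c("chl_a", "chl_b", "viola", "anthera", "zea",
                   "lutein", "beta_car", "neo")

#' Summarize the pre/post-recovery pigment sample pair of one dish
#'
#' @param samples Data frame with exactly two rows (recovery `"pre"` and
#'   `"post"`) for a single dish, with the eight pigment columns `chl_a`,
#'   `chl_b`, `viola`, `anthera`, `zea`, `lutein`, `beta_car`, `neo`
#'   (concentration per frond area) and optionally `dish_id`,
#'   `growth_ppfd`.
#' @return One-row data frame with `chl_ab`, `chl_a_over_b`, `vaz`
#'   (V+A+Z pool, pre/post mean), `total_car` (lutein + beta-carotene +
#'   V+A+Z + neoxanthin, pre/post mean), `z_frac_vaz_pre`,
#'   `z_frac_vaz_post` (zeaxanthin as a fraction of the xanthophyll-cycle
#'   pool per recovery state), `zea_pre`, `zea_post`, `zea` (= pre-recovery
#'   reported value), plus the stable individual pigments averaged.
#' @examples
#' s <- data.frame(recovery = c("pre", "post"),
#'                 chl_a = 300, chl_b = 100, viola = c(10, 16),
#'                 anthera = 2, zea = c(8, 2), lutein = c(10, 14),
#'                 beta_car = 5, neo = 3)
#' summarize_dish(s)$lutein  # 12
#' @export
summarize_dish <- function(samples) {
  stopifnot(is.data.frame(samples), "recovery" %in% names(samples),
            all(.pigment_cols %in% names(samples)))
  pre <- samples[samples$recovery == "pre", , drop = FALSE]
  post <- samples[samples$recovery == "post", , drop = FALSE]
  if (nrow(pre) != 1L || nrow(post) != 1L)
    stop("need exactly one pre-recovery and one post-recovery sample per dish")
  conc <- as.matrix(samples[, .pigment_cols])
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("pigment concentrations must be non-negative and finite")

  vaz_of <- function(s) s$viola + s$anthera + s$zea
  total_car_of <- function(s) s$lutein + s$beta_car + vaz_of(s) + s$neo
  avg <- function(col) (pre[[col]] + post[[col]]) / 2
  chl_ab <- avg("chl_a") + avg("chl_b")
  zfrac <- function(s) {
    v <- vaz_of(s)
    if (v == 0) NA_real_ else s$zea / v
  }

  out <- data.frame(
    chl_a = avg("chl_a"), chl_b = avg("chl_b"), chl_ab = chl_ab,
    chl_a_over_b = avg("chl_a") / avg("chl_b"),
    lutein = avg("lutein"), beta_car = avg("beta_car"), neo = avg("neo"),
    # pools averaged as pools: the V+A+Z sum is recovery-stable even
    # though its members interconvert
    vaz = (vaz_of(pre) + vaz_of(post)) / 2,
    total_car = (total_car_of(pre) + total_car_of(post)) / 2,
    zea_pre = pre$zea, zea_post = post$zea, zea = pre$zea,
    z_frac_vaz_pre = zfrac(pre), z_frac_vaz_post = zfrac(post))
  if ("dish_id" %in% names(samples))
    out <- cbind(dish_id = as.character(samples$dish_id[1L]), out,
                 stringsAsFactors = FALSE)
  if ("growth_ppfd" %in% names(samples))
    out$growth_ppfd <- samples$growth_ppfd[1L]
  out
}

#' Summarize a full pigment table, one row per dish
#'
#' @param pigments Long-format pigment table (one row per dish x recovery
#'   state) as produced by [generate_pigment_table()].
#' @return Data frame of per-dish summaries (see [summarize_dish()]).
#' @export
summarize_pigments <- function(pigments) {
  stopifnot("dish_id" %in% names(pigments))
  out <- do.call(rbind, lapply(split(pigments, pigments$dish_id), summarize_dish))
  rownames(out) <- NULL
  out[order(out$dish_id), , drop = FALSE]
}

#' Carotenoid-to-chlorophyll ratios
#'
#' Divides each carotenoid quantity of a pigment summary by total
#' chlorophyll a+b. Ratios are mol/mol only when the input table is on a
#' molar basis; the function performs no unit conversion.
#'
#' @param summary One or more rows from [summarize_dish()] /
#'   [summarize_pigments()].
#' @return Data frame with `lutein_per_chl`, `beta_car_per_chl`,
#'   `neo_per_chl`, `vaz_per_chl`, `total_car_per_chl`, `zea_per_chl`
#'   (pre-recovery zeaxanthin) and carried-over `dish_id`/`growth_ppfd`.
#' @export
per_chlorophyll <- function(summary) {
  stopifnot(all(c("chl_ab", "vaz", "total_car") %in% names(summary)))
  if (any(summary$chl_ab <= 0))
    stop("total chlorophyll must be positive to form per-chlorophyll ratios")
  out <- data.frame(
    lutein_per_chl = summary$lutein / summary$chl_ab,
    beta_car_per_chl = summary$beta_car / summary$chl_ab,
    neo_per_chl = summary$neo / summary$chl_ab,
    vaz_per_chl = summary$vaz / summary$chl_ab,
    total_car_per_chl = summary$total_car / summary$chl_ab,
    zea_per_chl = summary$zea / summary$chl_ab)
  for (col in c("dish_id", "growth_ppfd"))
    if (col %in% names(summary)) out[[col]] <- summary[[col]]
  out
}

#' Zeaxanthin retention by growth PPFD and recovery state
#'
#' Tabulates Z/(V+A+Z) — zeaxanthin as a fraction of the xanthophyll-cycle
#' pool — as mean and standard deviation per growth PPFD, separately for
#' the pre- and post-recovery samples. Dishes whose pool is empty yield an
#' undefined fraction and are flagged rather than dropped silently.
#'
#' @param summaries Per-dish summaries from [summarize_pigments()] (needs
#'   `growth_ppfd`, `z_frac_vaz_pre`, `z_frac_vaz_post`).
#' @return Data frame with `growth_ppfd`, `recovery`, `mean_z_frac`,
#'   `sd_z_frac`, `n`, `n_undefined`.
#' @export
zeaxanthin_retention <- function(summaries) {
  stopifnot(all(c("growth_ppfd", "z_frac_vaz_pre", "z_frac_vaz_post")
                %in% names(summaries)))
  rows <- list()
  for (ppfd in sort(unique(summaries$growth_ppfd))) {
    sub <- summaries[summaries$growth_ppfd == ppfd, ]
    for (state in c("pre", "post")) {
      z <- sub[[paste0("z_frac_vaz_", state)]]
      rows[[length(rows) + 1L]] <- data.frame(
        growth_ppfd = ppfd, recovery = state,
        mean_z_frac = mean(z, na.rm = TRUE),
        sd_z_frac = stats::sd(z, na.rm = TRUE),
        n = sum(!is.na(z)), n_undefined = sum(is.na(z)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
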