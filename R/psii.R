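# PSII fluorescence parameters and excitation-energy partitioning.
#
# Yields follow the standard PAM nomenclature: Fo/Fm are minimal/maximal
# fluorescence of dark-adapted fronds, F is steady-state fluorescence under
# the growth PPFD, and Fmp/Fop (Fm', Fo') are the light-adapted maximal and
# minimal yields. Derived quantities:
#   Fv/Fm    = (Fm - Fo)/Fm      potential maximal PSII efficiency (dark)
#   Fv'/Fm'  = (Fm' - Fo')/Fm'   efficiency of the open centers in light
#   1 - qP   = (F - Fo')/(Fm' - Fo')   fraction of closed (reduced) centers
# Energy partitioning (fractions of absorbed photons):
#   P = Fv'/Fm' x qP          used in photochemistry
#   D = 0.8 - Fv'/Fm'         dissipated thermally (photoprotection)
#   E = Fv'/Fm' x (1 - qP)    excess, removed by neither pathway
# so that P + D + E = 0.8, the assumed maximal fraction of absorbed photons
# usable by PSII photochemistry. D is only a valid dissipation estimate
# when dark Fv/Fm after a low-light recovery shows no photoinhibition.

#' Derive PSII fluorescence parameters from raw yields
#'
#' All arguments are vectorized; supply either the dark pair (`Fo`, `Fm`),
#' the light triple (`F`, `Fmp`, `Fop`), or both. Records where F falls
#' outside `[Fo', Fm']` (possible with instrument noise) are flagged via
#' `qp_out_of_range` and, when `clamp_qp = TRUE`, qP is clamped into
#' `[0, 1]`; by default nothing is clamped so problems stay visible.
#'
#' @param Fo,Fm Dark-adapted minimal and maximal yields (Fm > Fo > 0).
#' @param F,Fmp,Fop Light-adapted steady-state, maximal and minimal yields.
#' @param clamp_qp Clamp qP into `[0, 1]` when F strays outside
#'   `[Fo', Fm']`? Default `FALSE`.
#' @return A data frame with columns `FvFm`, `FvpFmp`, `qP`, `oneMinusQP`,
#'   `qp_degenerate` (Fm' = Fo': qP undefined) and `qp_out_of_range`.
#' @examples
#' derive_psii(Fo = 0.5, Fm = 2.5)$FvFm                     # 0.8
#' derive_psii(F = 1, Fmp = 2, Fop = 0.5)[c("FvpFmp", "qP")] # 0.75, 2/3
#' @export
derive_psii <- function(Fo = NA_real_, Fm = NA_real_, F = NA_real_,
                        Fmp = NA_real_, Fop = NA_real_, clamp_qp = FALSE) {
  n <- max(length(Fo), length(Fm), length(F), length(Fmp), length(Fop))
  Fo <- rep_len(Fo, n); Fm <- rep_len(Fm, n); F <- rep_len(F, n)
  Fmp <- rep_len(Fmp, n); Fop <- rep_len(Fop, n)
  if (any(c(Fo, Fm, F, Fmp, Fop) <= 0, na.rm = TRUE))
    stop("fluorescence yields must be positive")
  if (any(Fm <= Fo, na.rm = TRUE))
    stop("dark records require Fm > Fo")
  if (any(Fmp < Fop, na.rm = TRUE))
    stop("light records require Fm' >= Fo'")

  FvFm <- (Fm - Fo) / Fm
  FvpFmp <- (Fmp - Fop) / Fmp
  span <- Fmp - Fop
  degenerate <- !is.na(span) & span == 0
  oneMinusQP <- ifelse(degenerate, NA_real_, (F - Fop) / span)
  out_of_range <- !is.na(oneMinusQP) & (oneMinusQP < 0 | oneMinusQP > 1)
  if (any(out_of_range))
    warning(sum(out_of_range),
            " record(s) have F outside [Fo', Fm']; qP outside [0, 1]",
            if (clamp_qp) " (clamped)" else " (not clamped)")
  if (clamp_qp) oneMinusQP <- pmin(pmax(oneMinusQP, 0), 1)
  data.frame(FvFm = FvFm, FvpFmp = FvpFmp, qP = 1 - oneMinusQP,
             oneMinusQP = oneMinusQP, qp_degenerate = degenerate,
             qp_out_of_range = out_of_range)
}

#' Partition absorbed excitation energy at PSII
#'
#' Splits the assumed maximal usable fraction of absorbed photons
#' (`max_efficiency`, default 0.8) into photochemistry
#' `P = Fv'/Fm' x qP`, thermal dissipation `D = max_efficiency - Fv'/Fm'`
#' and excess `E = Fv'/Fm' x (1 - qP)`, plus the products of each fraction
#' with the incident PPFD. The identity `P + D + E = max_efficiency` holds
#' exactly. If `Fv'/Fm' > max_efficiency` the thermal term goes negative;
#' it is reported as-is with `valid = FALSE` rather than silently clamped.
#'
#' @param fvpfmp Light-adapted efficiency of open PSII centers (Fv'/Fm').
#' @param qp Photochemical quenching qP (fraction of open centers).
#' @param ppfd_i Incident PPFD (umol m^-2 s^-1) used for the rate products;
#'   `NA` skips the rates.
#' @param max_efficiency Maximal fraction of absorbed photons usable in
#'   photochemistry; 0.8 by convention.
#' @return Data frame with `P`, `D`, `E`, `rate_P`, `rate_D`, `rate_E`
#'   (umol m^-2 s^-1) and `valid`.
#' @examples
#' partition_energy(0.75, 2 / 3, ppfd_i = 700)
#' @export
partition_energy <- function(fvpfmp, qp, ppfd_i = NA_real_,
                             max_efficiency = 0.8) {
  stopifnot(is.numeric(fvpfmp), is.numeric(qp),
            is.numeric(max_efficiency), max_efficiency > 0)
  n <- max(length(fvpfmp), length(qp), length(ppfd_i))
  fvpfmp <- rep_len(fvpfmp, n); qp <- rep_len(qp, n)
  ppfd_i <- rep_len(ppfd_i, n)
  if (any(fvpfmp < 0, na.rm = TRUE) || any(qp < 0 | qp > 1, na.rm = TRUE))
    stop("need Fv'/Fm' >= 0 and qP in [0, 1]")
  P <- fvpfmp * qp
  D <- max_efficiency - fvpfmp
  E <- fvpfmp * (1 - qp)
  valid <- !is.na(D) & D >= 0
  if (any(!valid, na.rm = TRUE))
    warning("Fv'/Fm' exceeds max_efficiency for ", sum(!valid),
            " record(s): thermal dissipation fraction is negative")
  data.frame(P = P, D = D, E = E,
             rate_P = P * ppfd_i, rate_D = D * ppfd_i, rate_E = E * ppfd_i,
             valid = valid)
}

#' Recovery change in dark Fv/Fm
#'
#' Difference in dark-adapted Fv/Fm between a measurement taken immediately
#' on removal from the growth light (pre) and one after ~30 min of recovery
#' in low light (post). A positive value indicates relaxation of sustained
#' thermal dissipation; a post value that stays low flags photoinhibition.
#'
#' @param pre,post Single-row data frames from [derive_psii()] (dark
#'   records), or numeric Fv/Fm values.
#' @param dish_id_pre,dish_id_post Optional dish labels; if both given they
#'   must match.
#' @return `post FvFm - pre FvFm`.
#' @export
recovery_delta <- function(pre, post, dish_id_pre = NULL, dish_id_post = NULL) {
  if (!is.null(dish_id_pre) && !is.null(dish_id_post) &&
      !identical(dish_id_pre, dish_id_post))
    stop("pre and post records come from different dishes: ",
         dish_id_pre, " vs ", dish_id_post)
  f <- function(x) if (is.data.frame(x)) x$FvFm else x
  f(post) - f(pre)
}

#' Process a fluorescence yield table into PSII parameters per dish
#'
#' Consumes the long-format yield table (one row per dish x state, states
#' `light`, `dark_pre`, `dark_post`; columns `Fo`, `Fm`, `F`, `Fmp`, `Fop`)
#' and returns one row per dish with the dark efficiencies before and after
#' recovery, the light-adapted parameters, and the energy partition with
#' rate products at the growth PPFD. The partition is flagged valid only
#' when the post-recovery dark Fv/Fm reaches `recovery_floor` (default
#' 0.75), i.e. when there is no photoinhibitory inactivation — the stated
#' condition for reading `max_efficiency - Fv'/Fm'` as thermal dissipation.
#'
#' @param fluor Data frame with columns `dish_id`, `growth_ppfd`, `state`,
#'   `Fo`, `Fm`, `F`, `Fmp`, `Fop` (see [generate_fluorescence_table()]).
#' @param max_efficiency Passed to [partition_energy()].
#' @param recovery_floor Minimal post-recovery dark Fv/Fm for the
#'   partition to be considered valid.
#' @param clamp_qp Passed to [derive_psii()].
#' @return Data frame with one row per dish: `dish_id`, `growth_ppfd`,
#'   `FvFm_pre`, `FvFm_post`, `FvpFmp`, `qP`, `oneMinusQP`, `P`, `D`, `E`,
#'   `rate_P`, `rate_D`, `rate_E`, `partition_valid`, `recovered`.
#' @export
psii_table <- function(fluor, max_efficiency = 0.8, recovery_floor = 0.75,
                       clamp_qp = FALSE) {
  needed <- c("dish_id", "growth_ppfd", "state", "Fo", "Fm", "F", "Fmp", "Fop")
  stopifnot(all(needed %in% names(fluor)))
  rows <- lapply(split(fluor, fluor$dish_id), function(d) {
    get_state <- function(s) d[d$state == s, , drop = FALSE]
    light <- get_state("light"); pre <- get_state("dark_pre")
    post <- get_state("dark_post")
    if (nrow(light) != 1L || nrow(pre) != 1L || nrow(post) != 1L)
      stop("dish ", d$dish_id[1L],
           ": need exactly one light, one dark_pre and one dark_post row")
    dl <- derive_psii(F = light$F, Fmp = light$Fmp, Fop = light$Fop,
                      clamp_qp = clamp_qp)
    dpre <- derive_psii(Fo = pre$Fo, Fm = pre$Fm)
    dpost <- derive_psii(Fo = post$Fo, Fm = post$Fm)
    part <- partition_energy(dl$FvpFmp, dl$qP, ppfd_i = light$growth_ppfd,
                             max_efficiency = max_efficiency)
    recovered <- dpost$FvFm >= recovery_floor
    data.frame(dish_id = d$dish_id[1L], growth_ppfd = light$growth_ppfd,
               FvFm_pre = dpre$FvFm, FvFm_post = dpost$FvFm,
               FvpFmp = dl$FvpFmp, qP = dl$qP, oneMinusQP = dl$oneMinusQP,
               part[c("P", "D", "E", "rate_P", "rate_D", "rate_E")],
               partition_valid = part$valid & recovered & !dl$qp_degenerate,
               recovered = recovered, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
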