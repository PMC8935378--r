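#' Initialize the soil nutrient pools
#'
#' A quarter of the season-total soil supply is plant-available at
#' emergence; the remainder sits in the unreleased soil pool `S` and
#' becomes available at a constant rate over 0.9 of the season length.
#' The total supply of a nutrient includes its *extra* supply when the
#' fertilizer schedule applies a nonzero amount of both other nutrients
#' (extra supply is measured in omission treatments, where the applied
#' nutrients unlock additional uptake of the omitted one).
#'
#' @param supply a `cassava_supply` (g m^-2).
#' @param fertilizer fertilizer schedule data.frame (g m^-2), used only to
#'   decide which extra supplies are active.
#' @param extra_scale optional 0–1 scaling of the extra supplies,
#'   overriding the binary rule.
#' @return list of class `cassava_soil_npk` with per-nutrient vectors
#'   (named N, P, K): available pool `A`, unreleased soil pool `S_rem`,
#'   season-total soil supply `S_tot`, unreleased fertilizer pool `F_rem`,
#'   and cumulative bookkeeping (`cum_s_release`, `cum_f_avail`,
#'   `cum_uptake`, `f_applied`).
#' @examples
#' s <- initializeSoil(sitePreset("edo2016"), fertilizerSchedule())
#' s$A[["N"]] # 25% of 19.42
#' @export
initializeSoil <- function(supply, fertilizer = fertilizerSchedule(),
                           extra_scale = NULL) {
  applied <- c(N = sum(fertilizer$N), P = sum(fertilizer$P), K = sum(fertilizer$K))
  if (is.null(extra_scale)) {
    extra_scale <- c(
      N = as.numeric(applied[["P"]] > 0 && applied[["K"]] > 0),
      P = as.numeric(applied[["N"]] > 0 && applied[["K"]] > 0),
      K = as.numeric(applied[["N"]] > 0 && applied[["P"]] > 0)
    )
  } else {
    if (any(extra_scale < 0 | extra_scale > 1))
      stop("extra_scale must lie in [0, 1]")
    extra_scale <- rep_len(extra_scale, 3)
    names(extra_scale) <- NUTRIENTS
  }
  s_tot <- c(
    N = supply$base_N + extra_scale[["N"]] * supply$extra_N,
    P = supply$base_P + extra_scale[["P"]] * supply$extra_P,
    K = supply$base_K + extra_scale[["K"]] * supply$extra_K
  )
  if (any(s_tot < 0)) stop("negative soil supply after clamping")
  zero <- c(N = 0, P = 0, K = 0)
  structure(list(
    A = 0.25 * s_tot,
    S_rem = 0.75 * s_tot,
    S_tot = s_tot,
    F_rem = zero,
    cum_s_release = zero,
    cum_f_avail = zero,
    cum_uptake = zero,
    f_applied = zero
  ), class = "cassava_soil_npk")
}

#' Apply a fertilizer event
#'
#' Adds the event's N, P and K amounts to the unreleased fertilizer pools.
#'
#' @param state a `cassava_soil_npk` state.
#' @param event one-row data.frame (or list) with `N`, `P`, `K` in g m^-2.
#' @return updated state.
#' @export
applyFertilizer <- function(state, event) {
  add <- c(N = event$N, P = event$P, K = event$K)
  if (any(add < 0)) stop("fertilizer amounts must be >= 0")
  state$F_rem <- state$F_rem + add
  state$f_applied <- state$f_applied + add
  state
}

#' One day of soil nutrient release and uptake
#'
#' Implements the daily change in the plant-available pool per nutrient:
#' a constant release from the unreleased soil pool
#' (`0.75 * S_tot / (0.9 * SL)`, never more than what remains), plus
#' first-order fertilizer release `rf * F_rem * WLIMIT` of which the
#' fraction `Rec` reaches the available pool (the remainder is lost —
#' `Rec` is thereby the asymptotic fertilizer recovery), minus crop
#' uptake. Water limitation scales only the fertilizer release, not the
#' soil-pool release. All pools stay non-negative; uptake must already be
#' limited to the available pool by the caller.
#'
#' @param state a `cassava_soil_npk` state (after the day's fertilizer
#'   events).
#' @param params `cassava_params` (uses the `npk` block: `Rec_*`, `rf_*`,
#'   `DELT`).
#' @param SL season length (d).
#' @param wlimit water-limitation factor in \[0, 1\].
#' @param uptake named per-nutrient uptake rate (g m^-2 d^-1); defaults to
#'   zero.
#' @return list: updated `state`, the net available-pool rate `rate`
#'   (g m^-2 d^-1) and the day's gross releases `s_release`, `f_avail`.
#' @export
soilNutrientStep <- function(state, params, SL, wlimit,
                             uptake = c(N = 0, P = 0, K = 0)) {
  if (SL <= 0) stop("SL must be > 0")
  if (wlimit < 0 || wlimit > 1) stop("wlimit must lie in [0, 1]")
  npk <- params$npk
  delt <- npk$DELT
  rec <- c(N = npk$Rec_N, P = npk$Rec_P, K = npk$Rec_K)
  rf <- c(N = npk$rf_N, P = npk$rf_P, K = npk$rf_K)
  uptake <- uptake[NUTRIENTS]

  s_release <- pmin(0.75 * state$S_tot / (0.9 * SL), state$S_rem / delt)
  f_gross <- rf * state$F_rem * wlimit
  f_avail <- rec * f_gross
  rate <- s_release + f_avail - uptake

  a_new <- state$A + rate * delt
  if (any(uptake * delt > state$A + (s_release + f_avail) * delt + 1e-9))
    stop("uptake exceeds available pool for ",
         paste(NUTRIENTS[uptake * delt > state$A + (s_release + f_avail) * delt + 1e-9],
               collapse = ", "))
  state$A <- pmax(a_new, 0)
  state$S_rem <- pmax(state$S_rem - s_release * delt, 0)
  state$F_rem <- pmax(state$F_rem - f_gross * delt, 0)
  state$cum_s_release <- state$cum_s_release + s_release * delt
  state$cum_f_avail <- state$cum_f_avail + f_avail * delt
  state$cum_uptake <- state$cum_uptake + uptake * delt
  list(state = state, rate = rate, s_release = s_release, f_avail = f_avail)
}
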