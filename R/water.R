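#' Monod-type water limitation factor
#'
#' `WLIMIT = TRANRF / (K_WATER + TRANRF)`: a saturating transform of the
#' transpiration reduction factor that scales fertilizer nutrient release
#' under drought. Zero at full stress and bounded above by
#' `1 / (1 + K_WATER)`.
#'
#' @param tranrf transpiration reduction factor in \[0, 1\].
#' @param k_water Monod constant (> 0), default 0.2.
#' @return dimensionless factor in \[0, 1/(1+K_WATER)\].
#' @examples
#' wlimit(1, 0.2)   # ~0.833
#' wlimit(0.2, 0.2) # 0.5
#' @export
wlimit <- function(tranrf, k_water = 0.2) {
  if (any(tranrf < 0 | tranrf > 1)) stop("tranrf must lie in [0, 1]")
  if (any(k_water <= 0)) stop("k_water must be > 0")
  tranrf / (k_water + tranrf)
}

#' Initial soil water state
#'
#' Single-layer bucket at the initial rooted depth, starting at field
#' capacity (planting at the onset of rains).
#'
#' @param soil soil-water parameter block (see [defaultParameters()]).
#' @return list with rooted depth `rd` (m), water `wmm` (mm over the rooted
#'   zone) and the `dormancy` flag.
#' @export
initWaterState <- function(soil) {
  list(rd = soil$RDINIT, wmm = soil$WCFC * soil$RDINIT * 1000, dormancy = 0)
}

# Makkink-style reference evapotranspiration from radiation and mean
# temperature (mm/d); a simple configured method, adequate for the humid
# tropics this model targets.
referenceET <- function(srad, tmean) {
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  delta <- 4098 * es / (tmean + 237.3)^2
  gamma <- 0.066
  pmax(0, 0.65 * delta / (delta + gamma) * srad / 2.45)
}

#' One day of the tipping-bucket water balance
#'
#' Rain infiltrates up to field capacity (the excess drains); potential
#' evapotranspiration is split into soil evaporation and potential crop
#' transpiration by canopy cover; actual transpiration declines linearly
#' from its potential at a critical water fraction (set by the crop
#' transpiration coefficient) to zero at wilting point. `TRANRF` is the
#' actual/potential transpiration ratio (1 when potential transpiration is
#' zero). The rooted zone deepens with root growth; newly explored soil is
#' assumed at field capacity. Dormancy switches on when both the soil-water
#' and LAI thresholds are crossed and off when soil water recovers.
#'
#' @param state water state from [initWaterState()] or a previous step.
#' @param day one-row weather data.frame (or list) with `tmin`, `tmax`,
#'   `srad`, `rain`.
#' @param lai current leaf area index.
#' @param soil soil-water parameter block.
#' @param k canopy extinction coefficient (for cover partitioning).
#' @param growing whether roots are actively growing (crop sprouted).
#' @return list: updated `state`, `tranrf`, and the day's water fluxes
#'   (`drain`, `evap`, `tran`, `root_gain`, all mm) for balance checks.
#' @export
stepWaterBalance <- function(state, day, lai, soil, k = 0.7, growing = TRUE) {
  rd <- state$rd
  w <- state$wmm
  cap_fc <- soil$WCFC * rd * 1000
  cap_ad <- soil$WCAD * rd * 1000

  # infiltration and drainage
  w <- w + day$rain
  drain <- max(0, w - cap_fc)
  w <- w - drain

  # evaporative demand split by canopy cover
  et0 <- referenceET(day$srad, (day$tmin + day$tmax) / 2)
  cover <- 1 - exp(-k * lai)
  ptran <- et0 * cover
  pevap <- et0 * (1 - cover)

  wc <- w / (rd * 1000)
  # critical water fraction from the transpiration coefficient
  wccr <- soil$WCWP + (soil$WCFC - soil$WCWP) * ptran / (ptran + soil$TRANCO)
  tranrf <- if (ptran <= 0) 1 else
    min(1, max(0, (wc - soil$WCWP) / max(wccr - soil$WCWP, 1e-12)))
  tran <- ptran * tranrf
  evap <- pevap * min(1, max(0, (wc - soil$WCAD) / (soil$WCFC - soil$WCAD)))

  # never extract below air dry
  avail <- max(0, w - cap_ad)
  if (tran + evap > avail) {
    scale <- if (tran + evap > 0) avail / (tran + evap) else 0
    tran <- tran * scale
    evap <- evap * scale
  }
  w <- w - tran - evap

  # root deepening; new soil assumed at field capacity
  root_gain <- 0
  if (growing && rd < soil$RDMAX) {
    drd <- min(soil$RRDGR, soil$RDMAX - rd)
    root_gain <- soil$WCFC * drd * 1000
    rd <- rd + drd
    w <- w + root_gain
  }

  wc <- w / (rd * 1000)
  dormancy <- state$dormancy
  if (dormancy == 0 && wc < soil$DORM_WC && lai < soil$DORM_LAI) dormancy <- 1
  if (dormancy == 1 && wc > soil$DORM_WC_REC) dormancy <- 0

  list(state = list(rd = rd, wmm = w, dormancy = dormancy),
       tranrf = tranrf, drain = drain, evap = evap, tran = tran,
       root_gain = root_gain)
}
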