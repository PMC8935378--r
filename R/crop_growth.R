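#' Daily crop growth rate
#'
#' Radiation-use-efficiency growth under the stricter of water and
#' nutrient limitation, suppressed entirely during dormancy:
#' `dW/dt = RUE * PARint * min(TRANRF, NPKI) * (1 - dormancy)`.
#' The min form is exactly equivalent to applying `TRANRF` when
#' `TRANRF <= NPKI` and `NPKI` otherwise.
#'
#' @param rue radiation use efficiency (g DM MJ^-1 intercepted PAR).
#' @param parint intercepted PAR (MJ m^-2 d^-1).
#' @param tranrf transpiration reduction factor in \[0, 1\].
#' @param npki combined nutrient stress index in \[0, 1\].
#' @param dormancy binary dormancy flag.
#' @return growth rate (g DM m^-2 d^-1).
#' @examples
#' growthRate(3, 5, 0.9, 0.7, 0) # 10.5, nutrients bind
#' @export
growthRate <- function(rue, parint, tranrf, npki, dormancy = 0) {
  rue * parint * pmin(tranrf, npki) * (1 - dormancy)
}

#' Growth partitioning fractions along thermal time
#'
#' Baseline fractions come from the thermal-time partitioning table
#' (linear interpolation, constant beyond the ends). Stress — the stricter
#' of water and nutrient limitation — boosts the fine-root fraction in the
#' way drought does in the underlying water-limited model
#' (`max(1, 1/(0.5 + stress))`, capped), with the shoot fractions rescaled
#' so the four fractions still sum to 1.
#'
#' @param tsum temperature sum (degC d), scalar.
#' @param stress `min(TRANRF, NPKI)` in \[0, 1\]; 1 means no stress.
#' @param crop crop parameter block (uses `partition`, `FRT_STRESS_MAX`).
#' @return named fractions over `leaf, stem, so, rt`, summing to 1.
#' @export
partitionFractions <- function(tsum, stress, crop) {
  tab <- crop$partition
  base <- vapply(c("leaf", "stem", "so", "rt"), function(cc)
    stats::approx(tab$tsum, tab[[cc]], xout = tsum, rule = 2)$y, numeric(1))
  names(base) <- ORGANS
  frt <- base[["rt"]]
  mod <- max(1, 1 / (0.5 + stress))
  frt2 <- min(crop$FRT_STRESS_MAX, frt * mod)
  shoot <- base[c("leaf", "stem", "so")]
  if (sum(shoot) > 0)
    shoot <- shoot * (1 - frt2) / sum(shoot)
  c(shoot, rt = frt2)
}

#' Partition a day's growth over organs
#'
#' @param dw total growth (g DM m^-2 d^-1).
#' @param fractions named partitioning fractions summing to 1.
#' @return named organ increments summing exactly to `dw`.
#' @export
partitionGrowth <- function(dw, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("partition fractions must sum to 1")
  dw * fractions[ORGANS]
}

#' Daily leaf death rate
#'
#' The nutrient-stress component is `W_L * RDRNS * (1 - NPKI)`; it is
#' combined with the background rate (age senescence plus a drought
#' component) by maximum, not addition, to avoid double counting. The
#' result never drives the green leaf pool negative.
#'
#' @param w_leaf green leaf dry weight (g DM m^-2).
#' @param npki combined nutrient stress index.
#' @param tranrf transpiration reduction factor.
#' @param tsum temperature sum (degC d).
#' @param params `cassava_params`.
#' @return death rate (g DM m^-2 d^-1).
#' @examples
#' leafDeathRate(200, 0, 1, 2000, defaultParameters()) # 10 at full stress
#' @export
leafDeathRate <- function(w_leaf, npki, tranrf, tsum, params) {
  crop <- params$crop
  base_rdr <- (if (tsum >= crop$TSUM_SEN) crop$RDR_BASE else 0) +
    crop$RDR_WATER * (1 - tranrf)
  stress_rdr <- params$npk$RDRNS * (1 - npki)
  min(w_leaf * max(base_rdr, stress_rdr), w_leaf / params$npk$DELT)
}

#' Post-dormancy remobilization of storage-root reserves
#'
#' When dormancy ends, a configured fraction of the storage-root biomass
#' converts to new leaf biomass; the associated N, P and K transfer is
#' proportional to the storage-root biomass decrement, so whole-plant
#' nutrient totals are conserved.
#'
#' @param weights named organ dry weights (g DM m^-2).
#' @param amounts 4 x 3 matrix of organ nutrient amounts (g m^-2).
#' @param fraction storage-root fraction remobilized.
#' @return list with updated `weights` and `amounts`.
#' @export
dormancyRemobilize <- function(weights, amounts, fraction = 0.05) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  dec <- fraction * weights[["so"]]
  if (dec <= 0) return(list(weights = weights, amounts = amounts))
  weights[["so"]] <- weights[["so"]] - dec
  weights[["leaf"]] <- weights[["leaf"]] + dec
  moved <- fraction * amounts["so", ]
  amounts["so", ] <- amounts["so", ] - moved
  amounts["leaf", ] <- amounts["leaf", ] + moved
  list(weights = weights, amounts = amounts)
}
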