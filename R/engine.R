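#' Run the daily nutrient-limited growth simulation
#'
#' Euler integration with a one-day step and a fixed order of operations:
#' weather -> thermal increment -> water balance (TRANRF, WLIMIT, dormancy)
#' -> fertilizer events -> soil nutrient release -> plant min/max/optimum
#' amounts from the concentration lookups -> nutrient-equivalent demand and
#' supply -> nutrient-equivalent uptake -> per-nutrient uptake and
#' allocation -> nutrition indices and the combined stress index (with its
#' thermal-time gate) -> growth rate -> partitioning -> leaf death and
#' dead-leaf nutrient rerouting -> redistribution -> state update. All
#' rates are computed from start-of-day states; uptake is bounded by the
#' available pool *after* the day's release. Identical inputs give
#' identical output.
#'
#' @param params a `cassava_params` parameter set.
#' @param scenario a `cassava_scenario`.
#' @param limitNutrients if `FALSE` the combined stress index is forced to
#'   1 (nutrient bookkeeping still runs but never reduces growth),
#'   reproducing the water-limited baseline trajectory exactly.
#' @return A data.frame of class `cassava_sim`, one row per simulated day,
#'   with end-of-day states (organ weights, LAI, soil pools, plant
#'   amounts), the day's rates and the stress indices. Attributes `params`
#'   and `scenario` carry the inputs.
#' @examples
#' wx <- syntheticWeather(180, "wet", seed = 1)
#' sc <- cassavaScenario(sitePreset("edo2016"), weather = wx)
#' sim <- runSimulation(defaultParameters(), sc)
#' tail(sim$w_so, 1)
#' @export
runSimulation <- function(params, scenario, limitNutrients = TRUE) {
  validateParameters(params)
  stopifnot(inherits(scenario, "cassava_scenario"))
  npkp <- params$npk
  crop <- params$crop
  soilp <- params$soil
  delt <- npkp$DELT

  SL <- scenario$season_length
  wx <- scenario$weather[seq_len(SL), ]
  validateWeather(wx)

  ## drivers that depend only on weather and phenology: precompute
  dT <- thermalIncrement(wx$tmin, wx$tmax, crop$TBASE, delt)
  ts0 <- c(0, cumsum(dT))[seq_len(SL)]      # start-of-day TSUM
  cmin_day <- cmax_day <- array(
    0, c(SL, 4, 3), dimnames = list(NULL, ORGANS, NUTRIENTS))
  for (o in ORGANS) for (n in NUTRIENTS) {
    v <- interpolateConcentration(params$conc, o, n, ts0)
    cmin_day[, o, n] <- v$cmin
    cmax_day[, o, n] <- v$cmax
  }
  pf_base <- vapply(c("leaf", "stem", "so", "rt"), function(cc)
    stats::approx(crop$partition$tsum, crop$partition[[cc]],
                  xout = ts0, rule = 2)$y, numeric(SL))
  colnames(pf_base) <- ORGANS

  ## per-day fertilizer amounts (events at day 0 applied on day 1)
  fert_day <- matrix(0, SL, 3, dimnames = list(NULL, NUTRIENTS))
  fs <- scenario$fertilizer
  if (nrow(fs)) {
    dd <- pmin(pmax(fs$day, 1), SL)
    for (i in seq_len(nrow(fs)))
      fert_day[dd[i], ] <- fert_day[dd[i], ] + c(fs$N[i], fs$P[i], fs$K[i])
  }

  ## initial states
  soil_npk <- initializeSoil(scenario$supply, scenario$fertilizer)
  water <- initWaterState(soilp)
  weights <- c(leaf = 0, stem = 0, so = 0, rt = 0)
  w_dead <- 0
  amounts <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
  reserve <- as.numeric(scenario$cutting_npk)
  names(reserve) <- NUTRIENTS
  cum_cut <- c(N = 0, P = 0, K = 0)
  sprouted <- FALSE
  ov <- scenario$tranrf_override

  nut_cols <- unlist(lapply(
    c("A", "S", "F", "act", "min", "max", "opt", "up", "ni"),
    function(s) paste(s, NUTRIENTS, sep = "_")))
  cols <- c("day", "tsum", "dtsum", "tranrf", "wlimit", "dormancy",
            "rd", "wmm", "rain", "drain", "evap", "tran", "root_gain",
            "parint", "dw", "lai",
            "w_leaf", "w_dead_leaf", "w_stem", "w_so", "w_rt",
            nut_cols, "npki", "cut_release_N", "cut_release_P", "cut_release_K")
  rec <- matrix(NA_real_, SL, length(cols), dimnames = list(NULL, cols))

  for (d in seq_len(SL)) {
    wd <- list(tmin = wx$tmin[d], tmax = wx$tmax[d],
               srad = wx$srad[d], rain = wx$rain[d])
    tsum <- ts0[d]
    lai <- crop$SLA * weights[["leaf"]]

    ## water balance (or the bit-exact override pass-through)
    if (is.null(ov)) {
      prev_dorm <- water$dormancy
      ws <- stepWaterBalance(water, wd, lai, soilp, crop$K_EXT,
                             growing = sprouted)
      water <- ws$state
      tranrf <- ws$tranrf
      fluxes <- c(ws$drain, ws$evap, ws$tran, ws$root_gain)
      ## dormancy just ended: remobilize storage-root reserves to leaves
      if (prev_dorm == 1 && water$dormancy == 0 && weights[["so"]] > 0) {
        rem <- dormancyRemobilize(weights, amounts, crop$REMOB_FRACTION)
        weights <- rem$weights
        amounts <- rem$amounts
        lai <- crop$SLA * weights[["leaf"]]
      }
    } else {
      tranrf <- ov[d]
      fluxes <- c(0, 0, 0, 0)
    }
    dormancy <- water$dormancy
    wlim <- wlimit(tranrf, npkp$K_WATER)

    ## sprouting: the cutting forms the initial shoot; organ nutrient
    ## amounts are drawn from the cutting reserve following assimilate
    ## partitioning, at up to maximum concentration
    if (!sprouted && tsum >= crop$TSUM_SPROUT) {
      sprouted <- TRUE
      fr0 <- pf_base[d, ] / sum(pf_base[d, ])
      weights <- scenario$initial_biomass * fr0
      want <- cmax_day[d, , ] * weights
      for (n in NUTRIENTS) {
        need <- sum(want[, n])
        rel <- min(reserve[[n]], need)
        if (need > 0) amounts[, n] <- want[, n] * (rel / need)
        reserve[[n]] <- reserve[[n]] - rel
        cum_cut[[n]] <- cum_cut[[n]] + rel
      }
      lai <- crop$SLA * weights[["leaf"]]
    }

    ## fertilizer events, then soil release (uptake subtracted below)
    if (any(fert_day[d, ] > 0))
      soil_npk <- applyFertilizer(
        soil_npk, list(N = fert_day[d, "N"], P = fert_day[d, "P"],
                       K = fert_day[d, "K"]))
    rel <- soilNutrientStep(soil_npk, params, SL, wlim)
    soil_npk <- rel$state

    ## plant amounts, nutrient equivalents, uptake
    cmin_d <- matrix(cmin_day[d, , ], 4, 3, dimnames = list(ORGANS, NUTRIENTS))
    cmax_d <- matrix(cmax_day[d, , ], 4, 3, dimnames = list(ORGANS, NUTRIENTS))
    pa <- plantAmounts(weights, amounts, cmin_d, cmax_d, npkp$FR_MAX)
    ned <- nutrientEquivalentDemand(pa$act, pa$max)
    nes <- nutrientEquivalentSupply(soil_npk$A, pa$max)
    upr <- uptakeRates(ned, nes, pa$act, pa$max, soil_npk$A, params)
    up <- upr$up
    soil_npk$A <- soil_npk$A - up * delt
    soil_npk$cum_uptake <- soil_npk$cum_uptake + up * delt

    ## stress indices (gated by TSUM_NPKI)
    nid <- nutritionIndices(pa$act, pa$min, pa$opt, tsum, params)
    npki_val <- if (limitNutrients) nid$npki else 1

    ## growth, partitioning, leaf death
    parint <- interceptedPAR(wd$srad, lai, crop$K_EXT)
    dw <- if (sprouted) growthRate(crop$RUE, parint, tranrf, npki_val,
                                   dormancy) else 0
    stress <- min(tranrf, npki_val)
    ## same rule as partitionFractions(), on the precomputed base fractions
    frac <- {
      base <- pf_base[d, ]
      frt2 <- min(crop$FRT_STRESS_MAX, base[["rt"]] * max(1, 1 / (0.5 + stress)))
      shoot <- base[c("leaf", "stem", "so")]
      if (sum(shoot) > 0) shoot <- shoot * (1 - frt2) / sum(shoot)
      c(shoot, rt = frt2)
    }
    ginc <- partitionGrowth(dw, frac)
    death <- if (sprouted) leafDeathRate(weights[["leaf"]], npki_val,
                                         tranrf, tsum, params) else 0
    frac_dead <- if (weights[["leaf"]] > 0) death * delt / weights[["leaf"]] else 0

    ## nutrient transfers: uptake allocation, dead-leaf rerouting,
    ## redistribution, cutting-reserve release into new growth
    alloc <- allocateUptake(up, weights)
    reroute <- rerouteDeadLeafNutrients(frac_dead, amounts)
    redis <- redistributionRates(amounts, cmax_d * weights[ORGANS],
                                 npkp$TC_NPK_T)
    cutrel <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
    if (any(reserve > 0) && dw > 0) {
      need_mat <- cmax_d * pmax(ginc[ORGANS], 0) * delt
      for (n in NUTRIENTS) {
        need <- sum(need_mat[, n])
        relc <- min(reserve[[n]], need)
        if (need > 0 && relc > 0) {
          cutrel[, n] <- need_mat[, n] * (relc / need)
          reserve[[n]] <- reserve[[n]] - relc
          cum_cut[[n]] <- cum_cut[[n]] + relc
        }
      }
    }

    ## state update (all rates integrate with the same start-of-day states)
    weights <- weights + ginc * delt
    weights[["leaf"]] <- weights[["leaf"]] - death * delt
    w_dead <- w_dead + death * delt
    amounts <- amounts + (alloc + reroute + redis) * delt + cutrel
    if (any(amounts < 0)) {
      if (min(amounts) < -1e-9) {
        bad <- which(amounts < -1e-9, arr.ind = TRUE)[1, ]
        stop("negative nutrient amount on day ", d, ": ",
             ORGANS[bad[1]], "/", NUTRIENTS[bad[2]])
      }
      amounts[amounts < 0] <- 0
    }
    if (!all(is.finite(c(weights, amounts, soil_npk$A))))
      stop("non-finite state on day ", d)
    lai <- crop$SLA * weights[["leaf"]]

    rec[d, ] <- c(d, tsum + dT[d], dT[d], tranrf, wlim, dormancy,
                  water$rd, water$wmm, wd$rain, fluxes,
                  parint, dw, lai,
                  weights[["leaf"]], w_dead, weights[["stem"]],
                  weights[["so"]], weights[["rt"]],
                  soil_npk$A, soil_npk$S_rem, soil_npk$F_rem,
                  colSums(amounts), pa$min, pa$max, pa$opt, up, nid$ni,
                  npki_val, cum_cut)
  }

  out <- as.data.frame(rec)
  out$date <- wx$date
  out <- out[, c("day", "date", setdiff(cols, "day"))]
  attr(out, "params") <- params
  attr(out, "scenario") <- scenario
  attr(out, "soil_final") <- soil_npk
  class(out) <- c("cassava_sim", "data.frame")
  out
}

#' @export
print.cassava_sim <- function(x, ...) {
  n <- nrow(x)
  cat("<cassava_sim> ", n, " days\n", sep = "")
  cat(sprintf("  final DM (g/m2): storage roots %.1f, stems %.1f, green leaves %.1f (+%.1f dead)\n",
              x$w_so[n], x$w_stem[n], x$w_leaf[n], x$w_dead_leaf[n]))
  cat(sprintf("  final uptake (g/m2): N %.2f  P %.2f  K %.2f\n",
              x$act_N[n], x$act_P[n], x$act_K[n]))
  cat(sprintf("  days with NPKI < 1: %d; days with TRANRF < 1: %d\n",
              sum(x$npki < 1), sum(x$tranrf < 1)))
  invisible(x)
}

#' Write the per-day simulation output to CSV
#'
#' @param sim a `cassava_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSimulation <- function(sim, path) {
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}

#' Harvest-day extraction
#'
#' Pulls the rows at the given days after planting (e.g. roughly 4, 8 and
#' 14 months) from a daily simulation.
#'
#' @param sim a `cassava_sim`.
#' @param dap days after planting.
#' @return data.frame subset of `sim`.
#' @export
harvestRecords <- function(sim, dap = c(120, 240, 420)) {
  dap <- dap[dap <= nrow(sim)]
  as.data.frame(sim)[sim$day %in% dap, , drop = FALSE]
}
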