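#' Organ concentration matrices at a temperature sum
#'
#' Interpolates the min/max concentration lookup table for all four organs
#' and three nutrients at one temperature sum.
#'
#' @param tab concentration lookup table.
#' @param tsum temperature sum (degC d), scalar.
#' @return list of two 4 x 3 matrices `cmin`, `cmax` (rows: leaf, stem,
#'   so, rt; columns: N, P, K).
#' @export
concentrationMatrices <- function(tab, tsum) {
  cmin <- cmax <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
  for (o in ORGANS) for (n in NUTRIENTS) {
    v <- interpolateConcentration(tab, o, n, tsum)
    cmin[o, n] <- v$cmin
    cmax[o, n] <- v$cmax
  }
  list(cmin = cmin, cmax = cmax)
}

#' Whole-plant actual, minimum, maximum and optimum nutrient amounts
#'
#' Minimum and maximum amounts are concentration-times-weight sums over
#' the four living organs; the actual amount is the sum of the stored
#' per-organ nutrient amounts (not derived from concentrations); the
#' optimum is `Min + FR_MAX * (Max - Min)`.
#'
#' @param weights named organ dry weights (g DM m^-2) over
#'   `leaf, stem, so, rt`.
#' @param amounts 4 x 3 matrix of organ nutrient amounts (g m^-2).
#' @param cmin,cmax 4 x 3 concentration matrices
#'   (see [concentrationMatrices()]).
#' @param fr_max optimal fraction of the min-to-max span, default 0.8.
#' @return list of named per-nutrient vectors `act`, `min`, `max`, `opt`.
#' @export
plantAmounts <- function(weights, amounts, cmin, cmax, fr_max = 0.8) {
  if (any(weights < 0)) stop("organ weights must be >= 0")
  w <- weights[ORGANS]
  mn <- colSums(cmin * w)
  mx <- colSums(cmax * w)
  list(act = colSums(amounts), min = mn, max = mx,
       opt = mn + fr_max * (mx - mn))
}

#' Nutrient-equivalent demand
#'
#' Total crop demand expressed in N-equivalents: the N deficit plus the
#' relative P and K deficits scaled by the maximum N amount. Terms with a
#' zero maximum are zero (no biomass yet); the total is floored at zero.
#'
#' @param act,max named per-nutrient amounts (g m^-2).
#' @return demand in nutrient equivalents (g m^-2).
#' @examples
#' nutrientEquivalentDemand(c(N = 6, P = 0.6, K = 4), c(N = 10, P = 1, K = 8)) # 13
#' @export
nutrientEquivalentDemand <- function(act, max) {
  term <- function(x) if (max[[x]] > 0)
    (max[[x]] - act[[x]]) / max[[x]] * max[["N"]] else 0
  ned <- (if (max[["N"]] > 0) max[["N"]] - act[["N"]] else 0) +
    term("P") + term("K")
  max(ned, 0)
}

#' Nutrient-equivalent soil supply
#'
#' Plant-available soil pools expressed in N-equivalents, mirroring the
#' demand conversion: `A_N + A_P/Max_P * Max_N + A_K/Max_K * Max_N`.
#'
#' @param a named per-nutrient available pools (g m^-2).
#' @param max named per-nutrient maximum plant amounts (g m^-2).
#' @return supply in nutrient equivalents (g m^-2).
#' @export
nutrientEquivalentSupply <- function(a, max) {
  term <- function(x) if (max[[x]] > 0) a[[x]] / max[[x]] * max[["N"]] else 0
  a[["N"]] + term("P") + term("K")
}

#' Daily nutrient uptake rates
#'
#' The nutrient-equivalent uptake rate is `RNE * min(NES, NED)`; the
#' per-nutrient uptake is then limited by that rate (converted back via
#' `Max_x / Max_N`), by the nutrient's own unmet demand, and by its
#' available soil pool. All rates are non-negative.
#'
#' @param ned,nes nutrient-equivalent demand and supply (g m^-2).
#' @param act,max named per-nutrient plant amounts (g m^-2).
#' @param a named per-nutrient available soil pools (g m^-2).
#' @param params `cassava_params` (uses `RNE`, `DELT`).
#' @return list: `dneup` (g NE m^-2 d^-1) and named `up` (g m^-2 d^-1).
#' @export
uptakeRates <- function(ned, nes, act, max, a, params) {
  npk <- params$npk
  dneup <- npk$RNE * min(nes, ned)
  up <- vapply(NUTRIENTS, function(x) {
    if (max[["N"]] <= 0 || max[[x]] <= 0) return(0)
    max(0, min((max[[x]] - act[[x]]) / npk$DELT,
               a[[x]] / npk$DELT,
               max[[x]] / max[["N"]] * dneup))
  }, numeric(1))
  list(dneup = dneup, up = up)
}

#' Allocate uptake to organs proportionally to biomass
#'
#' @param up named per-nutrient uptake (g m^-2 d^-1).
#' @param weights named organ dry weights (g DM m^-2).
#' @return 4 x 3 matrix of organ increments summing to `up` per nutrient
#'   (all zero, with a warning, if total weight is zero).
#' @export
allocateUptake <- function(up, weights) {
  w <- weights[ORGANS]
  tot <- sum(w)
  inc <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
  if (tot <= 0) {
    if (any(up > 0)) warning("no biomass to allocate uptake to")
    return(inc)
  }
  share <- w / tot
  for (n in NUTRIENTS) inc[, n] <- up[[n]] * share
  inc
}

#' Inter-organ nutrient redistribution rates
#'
#' Organs are driven towards equal relative nutrient saturation: each
#' organ's proportional demand is the whole-plant actual amount shared in
#' proportion to the organ's contribution to the whole-plant maximum.
#' Transfer rates are the gap to that target times the relative
#' redistribution rate `1 / TC_NPK_T`; per nutrient the rates sum to zero
#' (pure redistribution).
#'
#' @param amounts 4 x 3 matrix of organ nutrient amounts (g m^-2).
#' @param max_contrib 4 x 3 matrix of organ contributions to the maximum
#'   amounts (`cmax * weight`).
#' @param tc translocation time coefficient (d), default 10.
#' @return 4 x 3 matrix of transfer rates (g m^-2 d^-1).
#' @export
redistributionRates <- function(amounts, max_contrib, tc = 10) {
  rates <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
  for (n in NUTRIENTS) {
    tot_max <- sum(max_contrib[, n])
    if (tot_max <= 0) next
    target <- sum(amounts[, n]) * max_contrib[, n] / tot_max
    rates[, n] <- (target - amounts[, n]) / tc
  }
  rates
}

#' Reroute nutrients out of dying leaves
#'
#' Dead leaves carry no nutrients: the N held in the dying leaf fraction
#' moves to the stems, P and K to the storage organs. Whole-plant totals
#' are unchanged.
#'
#' @param frac_dead fraction of the green leaf pool dying today (0–1).
#' @param amounts 4 x 3 matrix of organ nutrient amounts (g m^-2).
#' @return 4 x 3 matrix of transfers to *add* to `amounts`.
#' @export
rerouteDeadLeafNutrients <- function(frac_dead, amounts) {
  if (frac_dead < 0 || frac_dead > 1)
    stop("frac_dead must lie in [0, 1]")
  tr <- matrix(0, 4, 3, dimnames = list(ORGANS, NUTRIENTS))
  moved <- frac_dead * amounts["leaf", ]
  tr["leaf", ] <- -moved
  tr["stem", "N"] <- moved[["N"]]
  tr["so", "P"] <- moved[["P"]]
  tr["so", "K"] <- moved[["K"]]
  tr
}

#' Combined NPK stress index from the nutrition-index product
#'
#' The three per-nutrient nutrition indices are multiplied to account for
#' interacting limitations and passed through a saturating Monod-type
#' transform with constant `K_NI` and scaling `c = K_NI + 1` (so that no
#' stress maps to exactly 1 for any `K_NI`). When `K_NI <= KMAX` the
#' transform is applied to the product directly; when `K_NI > KMAX` it is
#' applied to the complement, which penalizes joint stress more strongly:
#' at a product of 0.8 with the default constants the index is 0.77.
#'
#' @param product product of the N, P and K nutrition indices, in \[0, 1\].
#' @param k_ni Monod constant, default 6.1.
#' @param kmax branch threshold, default 4.
#' @return combined index in \[0, 1\].
#' @examples
#' npki(0.8)     # ~0.77
#' npki(1, 42)   # exactly 1 for any K_NI
#' @export
npki <- function(product, k_ni = 6.1, kmax = 4) {
  if (any(product < 0 | product > 1)) stop("product must lie in [0, 1]")
  cc <- k_ni + 1
  out <- if (k_ni <= kmax) {
    cc * product / (k_ni + product)
  } else {
    1 - cc * (1 - product) / (k_ni + (1 - product))
  }
  pmin(1, pmax(0, out))
}

#' Per-nutrient nutrition indices and the combined NPK index
#'
#' `NI_x = (Act_x - Min_x) / (Opt_x - Min_x)`, clamped to \[0, 1\] (the
#' index saturates at 1 under luxury uptake). If an optimum equals its
#' minimum the index degenerates to 1 when the actual amount is at least
#' the minimum and 0 otherwise. The combined index is [npki()] of the
#' product, forced to 1 while the temperature sum is below `TSUM_NPKI`
#' (early growth runs on cutting reserves and limitations are not allowed
#' to reduce growth).
#'
#' @param act,min,opt named per-nutrient amounts (g m^-2).
#' @param tsum current temperature sum (degC d).
#' @param params `cassava_params`.
#' @return list: named `ni` vector and scalar `npki`.
#' @export
nutritionIndices <- function(act, min, opt, tsum, params) {
  npkp <- params$npk
  ni <- vapply(NUTRIENTS, function(x) {
    span <- opt[[x]] - min[[x]]
    if (span <= 0) return(if (act[[x]] >= min[[x]]) 1 else 0)
    min(1, max(0, (act[[x]] - min[[x]]) / span))
  }, numeric(1))
  value <- if (tsum < npkp$TSUM_NPKI) 1 else
    npki(prod(ni), npkp$K_NI, npkp$KMAX)
  list(ni = ni, npki = value)
}
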