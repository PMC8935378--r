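#' Site nutrient supply
#'
#' Season-total soil N, P and K supply (uptake measured in control plots)
#' plus the potential *extra* supply of each nutrient that becomes
#' accessible when the two other nutrients are applied (measured in
#' omission treatments). Negative measured extras are clamped to zero with
#' a warning: supply pools cannot be negative.
#'
#' @param base_N,base_P,base_K base supply.
#' @param extra_N,extra_P,extra_K potential additional supply.
#' @param units `"g_m2"` (default, internal units) or `"kg_ha"`.
#' @return A list of class `cassava_supply`, in g m^-2.
#' @examples
#' siteSupply(194.2, 19.9, 88.0, 62.7, 11.5, -27.9, units = "kg_ha")
#' @export
siteSupply <- function(base_N, base_P, base_K,
                       extra_N = 0, extra_P = 0, extra_K = 0,
                       units = c("g_m2", "kg_ha")) {
  units <- match.arg(units)
  v <- c(base_N = base_N, base_P = base_P, base_K = base_K,
         extra_N = extra_N, extra_P = extra_P, extra_K = extra_K)
  if (units == "kg_ha") v <- kgPerHaToGPerM2(v)
  if (any(v[1:3] < 0))
    stop("base supply must be non-negative: ",
         paste(names(v[1:3])[v[1:3] < 0], collapse = ", "))
  neg <- v[4:6] < 0
  if (any(neg)) {
    warning("negative extra supply clamped to 0: ",
            paste(names(v[4:6])[neg], collapse = ", "))
    v[4:6][neg] <- 0
  }
  structure(as.list(v), class = "cassava_supply")
}

#' Measured site supply presets
#'
#' Uptake-derived soil supply values for the Nigerian trial sites
#' (control-plot uptake plus additional uptake in omission treatments),
#' usable as scenario defaults. Names: `edo2016` (calibration site),
#' `benue2017`, `crossriver2017`, `edo2017`.
#'
#' @param site preset name.
#' @return A `cassava_supply` object.
#' @export
sitePreset <- function(site = c("edo2016", "benue2017", "crossriver2017", "edo2017")) {
  site <- match.arg(site)
  tab <- list(
    edo2016        = c(194.2, 19.9, 88.0, 62.7, 11.5, -27.9),
    benue2017      = c(56.5, 7.6, 61.9, 23.1, 4.3, 38.0),
    crossriver2017 = c(108.5, 11.1, 69.0, 35.8, 7.1, 53.8),
    edo2017        = c(133.6, 15.6, 59.2, 47.1, 47.1, 7.2)
  )[[site]]
  suppressWarnings(
    siteSupply(tab[1], tab[2], tab[3], tab[4], tab[5], tab[6], units = "kg_ha")
  )
}

#' Fertilizer application schedule
#'
#' One row per application event: day after planting and N, P, K amounts.
#'
#' @param day integer vector of days after planting (>= 0).
#' @param N,P,K amounts applied at each event.
#' @param units `"g_m2"` or `"kg_ha"`.
#' @return data.frame with columns `day`, `N`, `P`, `K` in g m^-2.
#' @export
fertilizerSchedule <- function(day = integer(), N = 0, P = 0, K = 0,
                               units = c("g_m2", "kg_ha")) {
  units <- match.arg(units)
  if (!length(day))
    return(data.frame(day = integer(), N = numeric(), P = numeric(), K = numeric()))
  ev <- data.frame(day = as.integer(day), N = N, P = P, K = K)
  if (any(ev$day < 0)) stop("fertilizer event day must be >= 0")
  if (any(ev[c("N", "P", "K")] < 0)) stop("fertilizer amounts must be >= 0")
  if (units == "kg_ha")
    ev[c("N", "P", "K")] <- lapply(ev[c("N", "P", "K")], kgPerHaToGPerM2)
  ev[order(ev$day), , drop = FALSE]
}

#' Split NPK application schedule for one treatment
#'
#' Builds a typical split schedule: P as a single basal dressing at the
#' first application day; N and K split equally over the application days.
#'
#' @param N,P,K season totals in kg ha^-1.
#' @param days application days after planting.
#' @return fertilizer schedule data.frame (g m^-2).
#' @export
npkSchedule <- function(N, P, K, days = c(30, 75)) {
  nd <- length(days)
  fertilizerSchedule(
    day = days,
    N = rep(N / nd, nd),
    P = c(P, rep(0, nd - 1)),
    K = rep(K / nd, nd),
    units = "kg_ha"
  )
}

#' Simulation scenario
#'
#' Bundles everything one run needs: site supply, fertilizer schedule,
#' weather, season length, and the initial cutting (its biomass and
#' nutrient reserve).
#'
#' @param supply a `cassava_supply`.
#' @param fertilizer a fertilizer schedule data.frame (g m^-2).
#' @param weather a weather data.frame (see [readWeather()] /
#'   [syntheticWeather()]).
#' @param season_length season length in days (planting to harvest); must
#'   be covered by the weather series. Defaults to the weather length.
#' @param planting_date `Date`; defaults to the first weather date.
#' @param initial_biomass g DM m^-2 of sprouting shoot formed from the
#'   cutting.
#' @param cutting_npk named numeric `c(N=, P=, K=)`: the cutting nutrient
#'   reserve (g m^-2) released to new growth following assimilate
#'   partitioning. Defaults are small, as for typical stake material.
#' @param tranrf_override optional numeric vector (one value per day in
#'   \[0,1\]) that replaces the simulated transpiration reduction factor
#'   day by day (test hook, bit-exact pass-through).
#' @return list of class `cassava_scenario`.
#' @export
cassavaScenario <- function(supply,
                            fertilizer = fertilizerSchedule(),
                            weather,
                            season_length = nrow(weather),
                            planting_date = weather$date[1],
                            initial_biomass = 25,
                            cutting_npk = c(N = 0.45, P = 0.05, K = 0.38),
                            tranrf_override = NULL) {
  stopifnot(inherits(supply, "cassava_supply"))
  if (season_length <= 0) stop("season_length must be > 0")
  if (nrow(weather) < season_length)
    stop("weather does not cover the season: ", nrow(weather),
         " day(s) for a ", season_length, "-day season")
  if (!all(c("N", "P", "K") %in% names(cutting_npk)))
    stop("cutting_npk must be a named vector with N, P and K")
  if (!is.null(tranrf_override)) {
    if (length(tranrf_override) < season_length)
      stop("tranrf_override shorter than season")
    if (any(tranrf_override < 0 | tranrf_override > 1))
      stop("tranrf_override values must lie in [0, 1]")
  }
  structure(list(
    supply = supply,
    fertilizer = fertilizer,
    weather = weather,
    season_length = as.integer(season_length),
    planting_date = planting_date,
    initial_biomass = initial_biomass,
    cutting_npk = cutting_npk[c("N", "P", "K")],
    tranrf_override = tranrf_override
  ), class = "cassava_scenario")
}

#' @export
print.cassava_scenario <- function(x, ...) {
  cat("<cassava_scenario> ", x$season_length, " days from ",
      format(x$planting_date), "\n", sep = "")
  s <- x$supply
  cat(sprintf("  supply (g/m2): N %.2f(+%.2f) P %.2f(+%.2f) K %.2f(+%.2f)\n",
              s$base_N, s$extra_N, s$base_P, s$extra_P, s$base_K, s$extra_K))
  cat("  fertilizer events:", nrow(x$fertilizer), "\n")
  invisible(x)
}

#' NPK treatment batteries
#'
#' `omissionBattery()` returns the classical five treatments — control
#' (no fertilizer), the three single-nutrient omissions (N0PfKf, NfP0Kf,
#' NfPfK0) and the full rate NfPfKf — at full rates of 300 kg N, 100 kg P
#' and 300 kg K ha^-1. `treatmentBattery()` returns a 12-treatment
#' factorial subset spanning 0–300 kg N, 0–100 kg P and 0–300 kg K ha^-1.
#'
#' @param days application days after planting passed to [npkSchedule()].
#' @return Named list of fertilizer schedules (g m^-2).
#' @export
omissionBattery <- function(days = c(30, 75)) {
  list(
    control = npkSchedule(0, 0, 0, days),
    N0PfKf  = npkSchedule(0, 100, 300, days),
    NfP0Kf  = npkSchedule(300, 0, 300, days),
    NfPfK0  = npkSchedule(300, 100, 0, days),
    NfPfKf  = npkSchedule(300, 100, 300, days)
  )
}

#' @rdname omissionBattery
#' @export
treatmentBattery <- function(days = c(30, 75)) {
  rates <- list(
    control      = c(0, 0, 0),
    N0PfKf       = c(0, 100, 300),
    NfP0Kf       = c(300, 0, 300),
    NfPfK0       = c(300, 100, 0),
    NfPfK60      = c(300, 100, 60),
    NfPfK120     = c(300, 100, 120),
    NfPfK180     = c(300, 100, 180),
    NfPfK240     = c(300, 100, 240),
    NfPfKf       = c(300, 100, 300),
    N150P40K180  = c(150, 40, 180),
    N150PfKf     = c(150, 100, 300),
    NfP40K60     = c(300, 40, 60)
  )
  lapply(rates, function(r) npkSchedule(r[1], r[2], r[3], days))
}
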