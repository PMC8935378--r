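#' Read a daily weather series
#'
#' CSV with header columns `date` (ISO-8601), `tmin`, `tmax`, `srad`
#' (global radiation, MJ m^-2 d^-1) and `rain` (mm d^-1), one row per day.
#' The series is returned chronologically sorted and must be gap-free;
#' duplicate or missing dates and non-numeric cells are reported as errors.
#'
#' @param path CSV file path.
#' @return data.frame with columns `date`, `tmin`, `tmax`, `srad`, `rain`.
#' @export
readWeather <- function(path) {
  wx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin", "tmax", "srad", "rain")
  miss <- setdiff(need, names(wx))
  if (length(miss))
    stop("weather file missing column(s): ", paste(miss, collapse = ", "))
  wx$date <- as.Date(wx$date)
  if (anyNA(wx$date)) stop("weather file has unparseable dates")
  for (cc in c("tmin", "tmax", "srad", "rain")) {
    wx[[cc]] <- suppressWarnings(as.numeric(wx[[cc]]))
    if (anyNA(wx[[cc]]))
      stop("non-numeric value in weather column ", cc)
  }
  wx <- wx[order(wx$date), need]
  dup <- wx$date[duplicated(wx$date)]
  if (length(dup))
    stop("duplicate weather date: ", paste(format(dup), collapse = ", "))
  gaps <- diff(as.integer(wx$date))
  if (any(gaps != 1)) {
    at <- wx$date[which(gaps != 1)[1]]
    stop("gap in weather series after ", format(at))
  }
  validateWeather(wx)
  rownames(wx) <- NULL
  wx
}

validateWeather <- function(wx) {
  if (any(wx$tmin > wx$tmax)) stop("weather has tmin > tmax")
  if (any(wx$srad < 0)) stop("weather has negative radiation")
  if (any(wx$rain < 0)) stop("weather has negative rain")
  invisible(wx)
}

#' Daily thermal-time increment
#'
#' Effective temperature above a base temperature:
#' `max(0, (tmin + tmax)/2 - tbase) * delt`. Never negative.
#'
#' @param tmin,tmax daily minimum / maximum temperature (degC); vectors
#'   allowed.
#' @param tbase base temperature (degC).
#' @param delt time step (d), default 1.
#' @return thermal time increment(s), degC d.
#' @examples
#' thermalIncrement(22, 32, 12) # 15
#' @export
thermalIncrement <- function(tmin, tmax, tbase, delt = 1) {
  pmax(0, (tmin + tmax) / 2 - tbase) * delt
}

#' Intercepted photosynthetically active radiation
#'
#' Beer's-law canopy interception of PAR, with PAR taken as half of global
#' radiation: `0.5 * srad * (1 - exp(-k * lai))`.
#'
#' @param srad global radiation (MJ m^-2 d^-1).
#' @param lai leaf area index (m2 m^-2), >= 0.
#' @param k canopy light extinction coefficient.
#' @return intercepted PAR (MJ m^-2 d^-1).
#' @examples
#' interceptedPAR(16, 2, 0.7) # ~6.03
#' @export
interceptedPAR <- function(srad, lai, k) {
  if (any(lai < 0)) stop("lai must be >= 0")
  0.5 * srad * (1 - exp(-k * lai))
}

# Evaluate an expression under a fixed RNG seed, restoring RNG state after.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic humid-tropical weather year
#'
#' Emulates a southern-Nigeria style season starting at the onset of rains:
#' warm temperatures with a small seasonal cycle, 8–24 MJ m^-2 d^-1 global
#' radiation, and a rainy season interrupted by a seasonal dry period
#' mid-season. Two profiles:
#' \describe{
#'   \item{`"wet"`}{abundant, well distributed rainfall (a ~3000 mm year
#'     with only a mild mid-season reduction); season totals over 420 days
#'     exceed 2000 mm.}
#'   \item{`"dry-spell"`}{the same climate with a hard ~90-day mid-season
#'     drought (days 160–250 carry ~1% of normal rain).}
#' }
#' The series is reproducible: the same seed yields the same series, and
#' the caller's RNG state is left untouched.
#'
#' @param n_days number of days (>= 1).
#' @param profile `"wet"` or `"dry-spell"`.
#' @param seed integer RNG seed.
#' @param start date of day 1 (planting at rain onset).
#' @return weather data.frame (`date`, `tmin`, `tmax`, `srad`, `rain`).
#' @export
syntheticWeather <- function(n_days, profile = c("wet", "dry-spell"),
                             seed = 1, start = as.Date("2016-05-24")) {
  profile <- match.arg(profile)
  if (n_days < 1) stop("n_days must be >= 1")
  d <- seq_len(n_days)
  withSeed(seed, {
    season <- sin(2 * pi * (d - 60) / 365)       # annual cycle
    tmin <- 21.5 + 1.2 * season + stats::rnorm(n_days, 0, 0.8)
    spread <- 8 + pmax(0, -2 * season) + stats::rnorm(n_days, 0, 1)
    tmax <- tmin + pmax(2, spread)
    srad <- pmin(24, pmax(8, 15 + 3 * season + stats::rnorm(n_days, 0, 1.5)))
    # rain: wet-day process with seasonally varying intensity; the seasonal
    # dry period (days ~160-280 after a May planting) is mild in the wet
    # profile and severe in the dry-spell profile
    midseason <- d > 160 & d <= 280
    wet_p <- ifelse(midseason, 0.45, 0.85)
    mu <- ifelse(midseason, 6, 12)              # mean wet-day rain, mm
    wet <- stats::runif(n_days) < wet_p
    rain <- ifelse(wet, stats::rgamma(n_days, shape = 0.9, scale = mu / 0.9), 0)
    if (profile == "dry-spell")
      rain[d > 160 & d <= 250] <- rain[d > 160 & d <= 250] * 0.01
    data.frame(date = start + d - 1, tmin = tmin, tmax = tmax,
               srad = srad, rain = rain)
  })
}
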