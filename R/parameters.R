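#' Default model parameters
#'
#' Returns the full parameter set of the nutrient-limited cassava growth
#' model: the NPK block (stress, uptake and fertilizer-release constants),
#' a base-crop block (radiation use efficiency, canopy and phenology
#' constants, thermal-time partitioning table) and a soil-water block
#' (bucket hydraulics and dormancy thresholds), plus the default organ
#' min/max nutrient-concentration lookup table.
#'
#' The NPK block defaults are the published constants for this model
#' family: maximum relative leaf death rate under nutrient stress
#' `RDRNS` = 0.05 d^-1, thermal-time gate `TSUM_NPKI` = 272 degC d,
#' optimal-concentration fraction `FR_MAX` = 0.8, maximum fertilizer
#' recoveries `Rec_N` = 0.75, `Rec_P` = 0.28, `Rec_K` = 0.7, relative
#' fertilizer release rates `rf_N` = 0.1, `rf_P` = 0.01, `rf_K` = 0.04 d^-1,
#' translocation time coefficient `TC_NPK_T` = 10 d, Monod constants
#' `K_NI` = 6.1 and `KMAX` = 4 for the combined stress index, `K_WATER` = 0.2
#' for the water-limitation factor, and maximum nutrient-equivalent uptake
#' rate `RNE` = 0.012 d^-1.
#'
#' The base-crop and soil-water blocks are published elsewhere for the
#' underlying water-limited model; the values here are stand-in defaults in
#' the physiological range for cassava in the humid tropics and are meant to
#' be overridden from a configuration file for site-specific work. The same
#' holds for the concentration lookup table (see
#' [defaultConcentrationTable()]).
#'
#' @return A list of class `cassava_params` with elements `npk`, `crop`,
#'   `soil` and `conc`.
#' @seealso [validateParameters()], [loadConfig()]
#' @examples
#' p <- defaultParameters()
#' p$npk$Rec_N
#' @export
defaultParameters <- function() {
  p <- list(
    npk = list(
      RDRNS     = 0.05,
      TSUM_NPKI = 272,
      FR_MAX    = 0.8,
      Rec_N     = 0.75,
      Rec_P     = 0.28,
      Rec_K     = 0.7,
      rf_N      = 0.1,
      rf_P      = 0.01,
      rf_K      = 0.04,
      TC_NPK_T  = 10,
      K_NI      = 6.1,
      KMAX      = 4,
      K_WATER   = 0.20,
      RNE       = 0.012,
      DELT      = 1
    ),
    crop = list(
      RUE        = 2.8,    # g DM MJ-1 intercepted PAR
      K_EXT      = 0.7,    # canopy light extinction coefficient
      SLA        = 0.015,  # m2 leaf g-1 DM
      TBASE      = 16,     # degC, base temperature for thermal time
      TSUM_SPROUT = 150,   # degC d, planting -> sprouting
      TSUM_BRANCH = 900,   # degC d, sprouting -> first branching
      TSUM_SEN    = 2200,  # degC d, onset of background leaf senescence
      RDR_BASE    = 0.008, # d-1, background relative leaf death rate
      RDR_WATER   = 0.03,  # d-1, drought component of leaf death
      FRT_STRESS_MAX = 0.6, # cap on fine-root partitioning under stress
      REMOB_FRACTION = 0.05, # storage-root fraction remobilized after dormancy
      # partitioning table: fractions of daily growth to leaf/stem/storage/root
      partition = data.frame(
        tsum = c(0, 150, 400, 1000, 2000, 3200, 4500),
        leaf = c(0.45, 0.45, 0.40, 0.30, 0.22, 0.10, 0.05),
        stem = c(0.25, 0.25, 0.32, 0.32, 0.28, 0.20, 0.15),
        so   = c(0.00, 0.00, 0.08, 0.28, 0.44, 0.66, 0.78),
        rt   = c(0.30, 0.30, 0.20, 0.10, 0.06, 0.04, 0.02)
      )
    ),
    soil = list(
      WCFC  = 0.32,  # volumetric water fraction at field capacity
      WCWP  = 0.15,  # wilting point
      WCSAT = 0.45,  # saturation
      WCAD  = 0.05,  # air dry
      RDINIT = 0.20, # m, initial rooted depth
      RDMAX  = 3.2,  # m, maximum rooted depth
      RRDGR  = 0.02, # m d-1, rooting depth growth rate
      TRANCO = 8,    # mm d-1, crop transpiration coefficient
      DORM_WC  = 0.16, # dormancy trigger: volumetric water below this ...
      DORM_LAI = 0.25, # ... and LAI below this
      DORM_WC_REC = 0.20 # dormancy released when water recovers above this
    ),
    conc = defaultConcentrationTable()
  )
  class(p) <- "cassava_params"
  p
}

#' @export
print.cassava_params <- function(x, ...) {
  cat("<cassava_params>\n")
  cat("  NPK block:  ", paste0(names(x$npk), "=", unlist(x$npk), collapse = ", "), "\n")
  cat("  crop block: RUE=", x$crop$RUE, " k=", x$crop$K_EXT, " SLA=", x$crop$SLA,
      " TBASE=", x$crop$TBASE, "\n", sep = "")
  cat("  partitioning breakpoints:", nrow(x$crop$partition), "\n")
  cat("  concentration table rows:", nrow(x$conc), "\n")
  invisible(x)
}

ORGANS    <- c("leaf", "stem", "so", "rt")
NUTRIENTS <- c("N", "P", "K")

#' Default organ min/max nutrient concentration lookup table
#'
#' Min and max N, P and K concentrations (g g^-1 DM) per organ as a function
#' of temperature sum, linearly interpolated at run time. Concentrations
#' dilute as the crop develops.
#'
#' These breakpoints are *synthetic stand-ins* chosen in the measured range
#' for cassava tissue: the measured curves behind the published model are in
#' supplementary material that is not reproduced here. Override them with
#' [readConcentrationTable()] for quantitative site work. Fine roots share
#' the stem curves.
#'
#' @return A data.frame with columns `organ`, `nutrient`, `tsum`, `cmin`,
#'   `cmax`.
#' @export
defaultConcentrationTable <- function() {
  bp <- c(0, 800, 2400, 4500)
  rows <- list(
    leaf = list(
      N = list(cmin = c(0.020, 0.017, 0.014, 0.012), cmax = c(0.065, 0.055, 0.045, 0.038)),
      P = list(cmin = c(0.0021, 0.0018, 0.0014, 0.0012), cmax = c(0.0070, 0.0060, 0.0048, 0.0040)),
      K = list(cmin = c(0.010, 0.008, 0.006, 0.005), cmax = c(0.032, 0.026, 0.020, 0.016))
    ),
    stem = list(
      N = list(cmin = c(0.009, 0.0072, 0.0048, 0.0042), cmax = c(0.030, 0.024, 0.016, 0.014)),
      P = list(cmin = c(0.0012, 0.0009, 0.0006, 0.00054), cmax = c(0.0040, 0.0030, 0.0020, 0.0018)),
      K = list(cmin = c(0.0080, 0.0060, 0.0036, 0.0030), cmax = c(0.027, 0.020, 0.012, 0.010))
    ),
    so = list(
      N = list(cmin = c(0.0042, 0.0035, 0.0029, 0.0029), cmax = c(0.014, 0.0115, 0.0095, 0.0095)),
      P = list(cmin = c(0.0009, 0.0007, 0.00055, 0.00055), cmax = c(0.0030, 0.0024, 0.0018, 0.0018)),
      K = list(cmin = c(0.0048, 0.0039, 0.0027, 0.0023), cmax = c(0.016, 0.013, 0.009, 0.0075))
    )
  )
  rows$rt <- rows$stem  # fine roots inherit stem curves
  out <- do.call(rbind, lapply(names(rows), function(o) {
    do.call(rbind, lapply(names(rows[[o]]), function(n) {
      data.frame(organ = o, nutrient = n, tsum = bp,
                 cmin = rows[[o]][[n]]$cmin, cmax = rows[[o]][[n]]$cmax)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a concentration lookup table
#'
#' CSV interface with columns `organ`, `nutrient`, `tsum`, `cmin`, `cmax`.
#'
#' @param path file path.
#' @return `readConcentrationTable` returns the validated data.frame.
#' @export
readConcentrationTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("organ", "nutrient", "tsum", "cmin", "cmax")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("concentration table missing column(s): ", paste(miss, collapse = ", "))
  validateConcentrationTable(tab)
  tab[need]
}

#' @rdname readConcentrationTable
#' @param tab concentration table data.frame.
#' @export
writeConcentrationTable <- function(tab, path) {
  validateConcentrationTable(tab)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

validateConcentrationTable <- function(tab) {
  if (any(!tab$organ %in% ORGANS))
    stop("unknown organ in concentration table: ",
         paste(unique(setdiff(tab$organ, ORGANS)), collapse = ", "))
  if (any(!tab$nutrient %in% NUTRIENTS))
    stop("unknown nutrient in concentration table: ",
         paste(unique(setdiff(tab$nutrient, NUTRIENTS)), collapse = ", "))
  if (any(tab$cmin > tab$cmax))
    stop("concentration table has cmin > cmax")
  if (any(tab$cmin < 0))
    stop("concentration table has negative concentrations")
  sp <- split(tab, list(tab$organ, tab$nutrient), drop = TRUE)
  for (s in sp) {
    if (any(diff(s$tsum) <= 0))
      stop("tsum breakpoints not strictly increasing for ",
           s$organ[1], "/", s$nutrient[1])
  }
  invisible(TRUE)
}

#' Interpolate organ nutrient concentrations at a temperature sum
#'
#' Linear interpolation between breakpoints, constant extrapolation beyond
#' the table ends.
#'
#' @param tab concentration table (see [defaultConcentrationTable()]).
#' @param organ one of `"leaf"`, `"stem"`, `"so"` (storage organ), `"rt"`
#'   (fine root).
#' @param nutrient one of `"N"`, `"P"`, `"K"`.
#' @param tsum temperature sum (degC d), may be a vector.
#' @return A list with numeric elements `cmin` and `cmax` (g g^-1 DM).
#' @examples
#' interpolateConcentration(defaultConcentrationTable(), "leaf", "N", 500)
#' @export
interpolateConcentration <- function(tab, organ, nutrient, tsum) {
  organ <- match.arg(organ, ORGANS)
  nutrient <- match.arg(nutrient, NUTRIENTS)
  s <- tab[tab$organ == organ & tab$nutrient == nutrient, ]
  if (!nrow(s))
    stop("no concentration entries for ", organ, "/", nutrient)
  cmin <- stats::approx(s$tsum, s$cmin, xout = tsum, rule = 2)$y
  cmax <- stats::approx(s$tsum, s$cmax, xout = tsum, rule = 2)$y
  list(cmin = cmin, cmax = cmax)
}

#' Validate a parameter set
#'
#' Checks the invariants of the parameter set: non-negative rates, bounded
#' fractions (`FR_MAX`, recoveries in \[0, 1\]), positive Monod constants,
#' unit time step, partitioning fractions summing to 1 at every breakpoint,
#' and a consistent concentration table. Violations raise an error naming
#' the offending field.
#'
#' @param params a `cassava_params` list.
#' @return `params`, invisibly, if valid.
#' @export
validateParameters <- function(params) {
  n <- params$npk
  chkRange <- function(value, name, lo = 0, hi = Inf, open.lo = FALSE) {
    if (is.null(value) || !is.finite(value))
      stop("parameter ", name, " is missing or not finite")
    if (value < lo || value > hi || (open.lo && value <= lo))
      stop("parameter ", name, " = ", value, " outside [", lo, ", ", hi, "]")
  }
  for (f in c("RDRNS", "TSUM_NPKI", "TC_NPK_T", "RNE", "rf_N", "rf_P", "rf_K"))
    chkRange(n[[f]], f)
  for (f in c("FR_MAX", "Rec_N", "Rec_P", "Rec_K"))
    chkRange(n[[f]], f, 0, 1)
  chkRange(n$K_NI, "K_NI", 0, Inf, open.lo = TRUE)
  chkRange(n$K_WATER, "K_WATER", 0, Inf, open.lo = TRUE)
  chkRange(n$KMAX, "KMAX", 0, Inf, open.lo = TRUE)
  if (!identical(as.numeric(n$DELT), 1))
    stop("parameter DELT must be 1 (daily time step)")
  cr <- params$crop
  for (f in c("RUE", "K_EXT", "SLA", "TSUM_SPROUT", "RDR_BASE"))
    chkRange(cr[[f]], f)
  part <- cr$partition
  tot <- rowSums(part[, c("leaf", "stem", "so", "rt")])
  if (any(abs(tot - 1) > 1e-9))
    stop("partition fractions do not sum to 1 at tsum = ",
         paste(part$tsum[abs(tot - 1) > 1e-9], collapse = ", "))
  so <- params$soil
  if (!(so$WCAD <= so$WCWP && so$WCWP < so$WCFC && so$WCFC <= so$WCSAT))
    stop("soil water fractions must satisfy WCAD <= WCWP < WCFC <= WCSAT")
  validateConcentrationTable(params$conc)
  invisible(params)
}

#' Convert between kg/ha and g/m2
#'
#' The internal unit system is g m^-2; kg ha^-1 is accepted at the I/O
#' boundary only. The conversion is an exact factor of 10.
#'
#' @param x numeric vector.
#' @return converted numeric vector.
#' @export
kgPerHaToGPerM2 <- function(x) x / 10

#' @rdname kgPerHaToGPerM2
#' @export
gPerM2ToKgPerHa <- function(x) x * 10
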