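#' Parse a quantity with an optional unit tag
#'
#' Accepts bare numbers (interpreted in `default_units`) or strings like
#' `"194.2 kg N ha-1"` / `"19.42 g m-2"`. Nutrient letters inside the unit
#' are ignored. Unknown unit tags are an error. The result is always in
#' g m^-2 (kg ha^-1 divides by exactly 10).
#'
#' @param x numeric or character scalar.
#' @param default_units units assumed for bare numbers.
#' @return numeric, g m^-2.
#' @examples
#' parseQuantity("194.2 kg N ha-1") # 19.42
#' @export
parseQuantity <- function(x, default_units = c("g_m2", "kg_ha")) {
  default_units <- match.arg(default_units)
  if (is.numeric(x))
    return(if (default_units == "kg_ha") kgPerHaToGPerM2(x) else x)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*(.*)$", x))[[1]]
  if (length(m) < 2 || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse quantity: ", x)
  value <- as.numeric(m[2])
  unit <- gsub("[ /^]|\\bN\\b|\\bP\\b|\\bK\\b", "", m[3])
  unit <- tolower(unit)
  if (unit == "")
    return(if (default_units == "kg_ha") kgPerHaToGPerM2(value) else value)
  if (unit %in% c("kgha-1", "kgha⁻¹", "kgha"))
    return(kgPerHaToGPerM2(value))
  if (unit %in% c("gm-2", "gm⁻²", "gm2"))
    return(value)
  stop("unknown unit tag in quantity: ", x)
}

## deep-merge user values into the default parameter list, complaining
## about unknown keys so typos do not silently fall back to defaults
mergeParams <- function(base, user, path = "parameters") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop("unknown configuration field: ", path, "$", key)
    if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
      base[[key]] <- mergeParams(base[[key]], user[[key]],
                                 paste0(path, "$", key))
    } else if (is.data.frame(base[[key]])) {
      base[[key]] <- as.data.frame(user[[key]])
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load a model configuration file
#'
#' Reads a YAML configuration with a `parameters` section (any subset of
#' the fields of [defaultParameters()], using the published parameter
#' names — `RDRNS`, `TSUM_NPKI`, `FR_MAX`, `Rec_N` ... — with missing
#' fields filled from the defaults) and an optional `scenario` section
#' (site supply, fertilizer schedule, weather source, season length,
#' cutting). Supply and fertilizer values may carry unit tags
#' (`units: kg_ha` or per-value strings such as `"194.2 kg N ha-1"`);
#' internally everything is g m^-2. An optional top-level
#' `concentrations` entry points to a concentration-table CSV (relative
#' paths resolve against the configuration file).
#'
#' @param path YAML file path.
#' @return list with elements `params` (validated `cassava_params`) and
#'   `scenario` (a `cassava_scenario`, or `NULL` if the file has no
#'   scenario section).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  params <- defaultParameters()
  if (!is.null(cfg$parameters)) {
    ## NPK constants live at the top level of the parameters section,
    ## under their published names; crop and soil blocks are nested
    user <- cfg$parameters
    blocks <- intersect(names(user), c("crop", "soil"))
    npk_fields <- setdiff(names(user), blocks)
    if (length(npk_fields))
      params$npk <- mergeParams(params$npk, user[npk_fields])
    for (b in blocks)
      params[[b]] <- mergeParams(params[[b]], user[[b]],
                                 paste0("parameters$", b))
  }
  class(params) <- "cassava_params"
  if (!is.null(cfg$concentrations)) {
    cpath <- cfg$concentrations
    if (!file.exists(cpath)) cpath <- file.path(base_dir, cfg$concentrations)
    params$conc <- readConcentrationTable(cpath)
  }
  validateParameters(params)

  scenario <- NULL
  sc <- cfg$scenario
  if (!is.null(sc)) {
    sunits <- if (is.null(sc$supply$units)) "g_m2" else sc$supply$units
    if (!sunits %in% c("g_m2", "kg_ha"))
      stop("unknown unit tag in scenario supply: ", sunits)
    getq <- function(nm) {
      v <- sc$supply[[nm]]
      if (is.null(v)) 0 else parseQuantity(v, sunits)
    }
    supply <- siteSupply(getq("base_N"), getq("base_P"), getq("base_K"),
                         getq("extra_N"), getq("extra_P"), getq("extra_K"))

    fert <- fertilizerSchedule()
    if (!is.null(sc$fertilizer)) {
      funits <- if (is.null(sc$fertilizer$units)) "g_m2" else sc$fertilizer$units
      ev <- sc$fertilizer$events
      if (length(ev)) {
        pick <- function(e, f) if (is.null(e[[f]])) 0 else e[[f]]
        fert <- fertilizerSchedule(
          day = vapply(ev, function(e) pick(e, "day"), numeric(1)),
          N = vapply(ev, function(e) pick(e, "N"), numeric(1)),
          P = vapply(ev, function(e) pick(e, "P"), numeric(1)),
          K = vapply(ev, function(e) pick(e, "K"), numeric(1)),
          units = funits)
      }
    }

    wspec <- sc$weather
    weather <- if (is.character(wspec)) {
      wpath <- if (file.exists(wspec)) wspec else file.path(base_dir, wspec)
      readWeather(wpath)
    } else if (!is.null(wspec$file)) {
      wpath <- if (file.exists(wspec$file)) wspec$file else
        file.path(base_dir, wspec$file)
      readWeather(wpath)
    } else if (!is.null(wspec$synthetic)) {
      n <- if (is.null(wspec$n_days)) sc$season_length else wspec$n_days
      syntheticWeather(n, wspec$synthetic,
                       seed = if (is.null(wspec$seed)) 1 else wspec$seed)
    } else stop("scenario weather must be a file or a synthetic profile")

    cut <- c(N = 0.36, P = 0.036, K = 0.30)
    if (!is.null(sc$cutting))
      cut[names(sc$cutting)] <- unlist(sc$cutting)
    scenario <- cassavaScenario(
      supply = supply, fertilizer = fert, weather = weather,
      season_length = if (is.null(sc$season_length)) nrow(weather) else
        sc$season_length,
      planting_date = if (is.null(sc$planting_date)) weather$date[1] else
        as.Date(sc$planting_date),
      initial_biomass = if (is.null(sc$initial_biomass)) 10 else
        sc$initial_biomass,
      cutting_npk = cut)
  }
  list(params = params, scenario = scenario)
}

#' Write a configuration file
#'
#' Serializes a parameter set (and optionally a scenario) to YAML so that
#' [loadConfig()] reads back an identical parameter set. When a scenario
#' is given its weather series is written to a sidecar CSV next to the
#' configuration file.
#'
#' @param params a `cassava_params`.
#' @param path output YAML path.
#' @param scenario optional `cassava_scenario`.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(params, path, scenario = NULL) {
  validateParameters(params)
  crop <- params$crop
  crop$partition <- as.list(crop$partition)
  cfg <- list(parameters = list())
  cfg$parameters <- c(params$npk, list(crop = crop, soil = params$soil))
  conc_path <- paste0(tools::file_path_sans_ext(path), "_concentrations.csv")
  writeConcentrationTable(params$conc, conc_path)
  cfg$concentrations <- basename(conc_path)
  if (!is.null(scenario)) {
    w_path <- paste0(tools::file_path_sans_ext(path), "_weather.csv")
    utils::write.csv(scenario$weather, w_path, row.names = FALSE)
    s <- scenario$supply
    cfg$scenario <- list(
      supply = list(units = "g_m2",
                    base_N = s$base_N, base_P = s$base_P, base_K = s$base_K,
                    extra_N = s$extra_N, extra_P = s$extra_P,
                    extra_K = s$extra_K),
      fertilizer = list(
        units = "g_m2",
        events = lapply(seq_len(nrow(scenario$fertilizer)), function(i)
          as.list(scenario$fertilizer[i, ]))),
      weather = list(file = basename(w_path)),
      season_length = scenario$season_length,
      planting_date = format(scenario$planting_date),
      initial_biomass = scenario$initial_biomass,
      cutting = as.list(scenario$cutting_npk)
    )
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
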