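test_that("published constants are the defaults and pass validation", {
  p <- defaultParameters()
  expect_silent(validateParameters(p))
  expect_equal(
    unlist(p$npk[c("RDRNS", "TSUM_NPKI", "FR_MAX", "Rec_N", "Rec_P", "Rec_K",
                   "rf_N", "rf_P", "rf_K", "TC_NPK_T", "K_NI", "KMAX",
                   "K_WATER", "RNE", "DELT")]),
    c(RDRNS = 0.05, TSUM_NPKI = 272, FR_MAX = 0.8, Rec_N = 0.75,
      Rec_P = 0.28, Rec_K = 0.7, rf_N = 0.1, rf_P = 0.01, rf_K = 0.04,
      TC_NPK_T = 10, K_NI = 6.1, KMAX = 4, K_WATER = 0.20, RNE = 0.012,
      DELT = 1))
})

test_that("validation names the offending field", {
  p <- defaultParameters()
  p$npk$FR_MAX <- 1.3
  expect_error(validateParameters(p), "FR_MAX")
  p <- defaultParameters()
  p$npk$K_NI <- 0
  expect_error(validateParameters(p), "K_NI")
  p <- defaultParameters()
  p$crop$partition$leaf[2] <- p$crop$partition$leaf[2] + 0.1
  expect_error(validateParameters(p), "sum to 1")
  p <- defaultParameters()
  p$conc$cmin[5] <- p$conc$cmax[5] + 1
  expect_error(validateParameters(p), "cmin > cmax")
})

test_that("concentration interpolation is linear, clamped and keyed", {
  tab <- data.frame(organ = "leaf", nutrient = "N",
                    tsum = c(100, 300),
                    cmin = c(0.02, 0.01), cmax = c(0.06, 0.04))
  at <- interpolateConcentration(tab, "leaf", "N", 200)   # midway
  expect_equal(at$cmin, 0.015)
  expect_equal(at$cmax, 0.05)
  at_bp <- interpolateConcentration(tab, "leaf", "N", 300)  # breakpoint
  expect_equal(at_bp$cmin, 0.01)
  expect_equal(at_bp$cmax, 0.04)
  beyond <- interpolateConcentration(tab, "leaf", "N", 1e4) # clamped
  expect_equal(beyond$cmax, 0.04)
  before <- interpolateConcentration(tab, "leaf", "N", 0)
  expect_equal(before$cmax, 0.06)
  expect_error(interpolateConcentration(tab, "leaf", "Mg", 100))
  expect_error(interpolateConcentration(tab, "stem", "N", 100), "stem")
})

test_that("unit conversion is an exact factor of ten both ways", {
  x <- c(194.2, 0, 62.7, 1e6)
  expect_identical(kgPerHaToGPerM2(x), x / 10)
  expect_identical(gPerM2ToKgPerHa(kgPerHaToGPerM2(x)), x)
  expect_equal(parseQuantity("194.2 kg N ha-1"), 19.42)
  expect_equal(parseQuantity("19.42 g m-2"), 19.42)
  expect_equal(parseQuantity(194.2, "kg_ha"), 19.42)
  expect_error(parseQuantity("194.2 furlongs"), "unit tag")
})

test_that("a configuration round-trips to an identical parameter set", {
  p <- defaultParameters()
  p$npk$K_NI <- 5.5
  p$crop$RUE <- 3.1
  dir <- withr::local_tempdir()
  path <- file.path(dir, "config.yml")
  writeConfig(p, path)
  back <- loadConfig(path)
  expect_equal(back$params$npk, p$npk, tolerance = 1e-12)
  expect_equal(back$params$crop[names(back$params$crop) != "partition"],
               p$crop[names(p$crop) != "partition"], tolerance = 1e-12)
  expect_equal(as.data.frame(back$params$crop$partition), p$crop$partition,
               tolerance = 1e-12)
  expect_equal(back$params$soil, p$soil, tolerance = 1e-12)
  expect_equal(back$params$conc$cmax, p$conc$cmax, tolerance = 1e-12)
})

test_that("missing fields fill with defaults; supply strings carry units", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "partial.yml")
  writeLines(c(
    "parameters:",
    "  RDRNS: 0.06",
    "scenario:",
    "  season_length: 40",
    "  supply:",
    "    base_N: 194.2 kg N ha-1",
    "    base_P: 19.9 kg P ha-1",
    "    base_K: 8.8",
    "  weather:",
    "    synthetic: wet",
    "    seed: 7",
    "    n_days: 40"), path)
  got <- loadConfig(path)
  expect_equal(got$params$npk$RDRNS, 0.06)
  expect_equal(got$params$npk$Rec_N, 0.75)   # untouched default
  expect_equal(got$scenario$supply$base_N, 19.42)
  expect_equal(got$scenario$supply$base_P, 1.99)
  expect_equal(got$scenario$supply$base_K, 8.8)  # bare number is g/m2
  expect_error(loadConfig(file.path(dir, "nope.yml")), "not found")

  writeLines(c("parameters:", "  REC_X: 1"), path)
  expect_error(loadConfig(path), "REC_X")
})

test_that("negative measured extra supply clamps to zero with a warning", {
  expect_warning(s <- siteSupply(194.2, 19.9, 88, -27.9, 0, -1, units = "kg_ha"),
                 "extra")
  expect_equal(s$extra_N, 0)
  expect_equal(s$extra_K, 0)
  expect_equal(s$base_N, 19.42)
  expect_error(siteSupply(-1, 1, 1), "base")
})
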