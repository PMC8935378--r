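# Shared fixtures, built in code. Weather and battery simulations are
# cached per test run because several files reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

wetWeather420 <- function() fixture("wx420", function()
  syntheticWeather(420, "wet", seed = 1))

wetWeather200 <- function() fixture("wx200", function()
  syntheticWeather(200, "wet", seed = 1))

edoScenario <- function(fert = fertilizerSchedule(), weather = wetWeather420(),
                        ...) {
  cassavaScenario(sitePreset("edo2016"), fert, weather = weather, ...)
}

# a scenario in which no nutrient can ever bind: saturating soil pools and
# a saturating cutting reserve
saturatedScenario <- function(weather = wetWeather420()) {
  cassavaScenario(siteSupply(1e5, 1e4, 1e5), weather = weather,
                  cutting_npk = c(N = 1e5, P = 1e4, K = 1e5))
}

omissionSims <- function() fixture("omission_sims", function() {
  p <- defaultParameters()
  lapply(omissionBattery(), function(f)
    runSimulation(p, edoScenario(f)))
})

# uniform concentration matrices for unit-level crop tests
flatConc <- function(cmin, cmax) {
  organs <- c("leaf", "stem", "so", "rt")
  nutrients <- c("N", "P", "K")
  list(cmin = matrix(cmin, 4, 3, dimnames = list(organs, nutrients)),
       cmax = matrix(cmax, 4, 3, dimnames = list(organs, nutrients)))
}
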