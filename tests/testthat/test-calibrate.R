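test_that("rmse is the root mean squared difference", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_equal(rmse(10, 13), 3)
  expect_error(rmse(numeric(0), numeric(0)))
  expect_error(rmse(1:3, 1:2))
})

# minimal stand-ins for simulation output: evaluateSim only reads $day and
# the observation-variable columns
fakeSim <- function(days, so, actN = so / 100) {
  data.frame(day = days, w_so = so, act_N = actN)
}

test_that("evaluation reports RMSEP, R2 and slope with exclusion filtering", {
  obs <- data.frame(
    treatment = rep(c("a", "b", "ctrl"), each = 2),
    dap = rep(c(100, 200), 3),
    variable = "root_dm",
    value = c(100, 400, 150, 500, 50, 120))
  sims <- list(a = fakeSim(c(100, 200), c(100, 400)),
               b = fakeSim(c(100, 200), c(150, 500)),
               ctrl = fakeSim(c(100, 200), c(999, 999)))
  perfect <- evaluateSim(sims, obs, exclude = "ctrl")
  expect_equal(perfect$rmsep, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$slope, 1)

  # constant shift: RMSEP is the shift, the slope stays 1
  shifted <- sims
  shifted$a$w_so <- shifted$a$w_so + 25
  shifted$b$w_so <- shifted$b$w_so + 25
  ev <- evaluateSim(shifted, obs, exclude = "ctrl")
  expect_equal(ev$rmsep, 25)
  expect_equal(ev$slope, 1)
  expect_equal(ev$n, 4)

  # without the filter the deliberately wrong control enters the pairing
  all_in <- evaluateSim(sims, obs)
  expect_equal(all_in$n, 6)
  expect_gt(all_in$rmsep, 100)
})

test_that("synthetic observations are exact at zero noise and reproducible", {
  p <- defaultParameters()
  scens <- list(ctrl = edoScenario(weather = wetWeather200()))
  obs <- syntheticObservations(p, scens, sample_days = c(60, 120, 180),
                               noise_cv = 0)
  sim <- runSimulation(p, scens$ctrl)
  expect_equal(obs$value[obs$variable == "root_dm"],
               sim$w_so[c(60, 120, 180)])
  expect_equal(obs$value[obs$variable == "uptake_N"],
               sim$act_N[c(60, 120, 180)])
  a <- syntheticObservations(p, scens, noise_cv = 0.2, seed = 9,
                             sample_days = c(120, 180))
  b <- syntheticObservations(p, scens, noise_cv = 0.2, seed = 9,
                             sample_days = c(120, 180))
  expect_identical(a, b)
  expect_false(all(a$value == obs$value[obs$dap %in% c(120, 180)]))
})

test_that("the noise model delivers the requested coefficient of variation", {
  p <- defaultParameters()
  scens <- list(ctrl = edoScenario(weather = wetWeather200()))
  days <- seq(100, 199, by = 2)
  clean <- syntheticObservations(p, scens, sample_days = days, noise_cv = 0)
  noisy <- syntheticObservations(p, scens, sample_days = days, noise_cv = 0.1,
                                 seed = 4)
  ratio <- noisy$value / clean$value
  expect_equal(length(ratio), 200)
  expect_lt(abs(sd(ratio) - 0.1), 0.02)
  expect_lt(abs(mean(ratio) - 1), 0.03)
})

test_that("the calibration objective is minimal at the generating triple", {
  p <- defaultParameters()
  scens <- list(full = edoScenario(npkSchedule(300, 100, 300),
                                   weather = wetWeather200(),
                                   season_length = 180))
  obs <- syntheticObservations(p, scens, sample_days = c(90, 180),
                               noise_cv = 0)
  fit <- calibrateNPKI(p, scens, obs,
                       grid = list(K_NI = c(3, 6.1, 9), KMAX = c(4, 7),
                                   TSUM_NPKI = c(172, 272, 372)),
                       simplex = FALSE)
  expect_equal(unname(fit$par), c(6.1, 4, 272))
  expect_lt(fit$objective, 1e-10)
  expect_true(all(fit$trace$objective >= fit$objective))
  expect_equal(fit$n_eval, 18)
})

test_that("the objective does not depend on treatment order", {
  p <- defaultParameters()
  scens <- list(
    ctrl = edoScenario(weather = wetWeather200(), season_length = 150),
    full = edoScenario(npkSchedule(300, 100, 300),
                       weather = wetWeather200(), season_length = 150))
  obs <- syntheticObservations(p, scens, sample_days = c(75, 150),
                               noise_cv = 0)
  one_point <- list(K_NI = 4, KMAX = 4, TSUM_NPKI = 272)
  f1 <- calibrateNPKI(p, scens, obs, grid = one_point, simplex = FALSE)
  f2 <- calibrateNPKI(p, rev(scens), obs[nrow(obs):1, ], grid = one_point,
                      simplex = FALSE)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-12)
})

test_that("a truth outside the bounds is recovered at the nearest boundary", {
  p <- defaultParameters()
  scens <- list(full = edoScenario(npkSchedule(300, 100, 300),
                                   weather = wetWeather200(),
                                   season_length = 180))
  truth <- p
  truth$npk$K_NI <- 2
  obs <- syntheticObservations(truth, scens, sample_days = c(90, 180),
                               noise_cv = 0)
  fit <- calibrateNPKI(p, scens, obs,
                       lower = c(K_NI = 3, KMAX = 4, TSUM_NPKI = 172),
                       upper = c(K_NI = 10, KMAX = 8, TSUM_NPKI = 372),
                       grid = list(K_NI = c(3, 6.1, 10), KMAX = 4,
                                   TSUM_NPKI = 272),
                       simplex = FALSE)
  expect_equal(unname(fit$par[[1]]), 3)   # boundary nearest the truth
  # and with the truth inside a grid, it wins
  fit2 <- calibrateNPKI(p, scens, obs,
                        grid = list(K_NI = c(2, 3, 6.1), KMAX = 4,
                                    TSUM_NPKI = 272),
                        simplex = FALSE)
  expect_equal(unname(fit2$par[[1]]), 2)
  expect_lt(fit2$objective, 1e-10)
  # bounds must always contain the published defaults
  expect_error(calibrateNPKI(p, scens, obs,
                             lower = c(K_NI = 7, KMAX = 4, TSUM_NPKI = 172),
                             upper = c(K_NI = 10, KMAX = 8, TSUM_NPKI = 372)),
               "default")
})

test_that("observation files round-trip with unit handling", {
  dir <- withr::local_tempdir()
  obs <- data.frame(treatment = "t1", dap = c(120, 240),
                    variable = "root_dm", value = c(1000, 2500), sd = c(10, 20))
  path <- file.path(dir, "obs.csv")
  write.csv(obs, path, row.names = FALSE)
  back <- readObservations(path)
  expect_equal(back$value, obs$value)
  back_kg <- readObservations(path, units = "kg_ha")
  expect_equal(back_kg$value, obs$value / 10)
  obs_bad <- obs; obs_bad$variable <- "yield"
  write.csv(obs_bad, path, row.names = FALSE)
  expect_error(readObservations(path), "yield")
  obs_dup <- rbind(obs, obs[1, ])
  write.csv(obs_dup, path, row.names = FALSE)
  expect_error(readObservations(path), "duplicate")
})
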