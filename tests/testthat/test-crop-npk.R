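test_that("plant amounts combine stored amounts with concentration bounds", {
  cm <- flatConc(0.01, 0.04)
  w0 <- c(leaf = 0, stem = 0, so = 0, rt = 0)
  a0 <- matrix(0, 4, 3, dimnames = dimnames(cm$cmin))
  pa <- plantAmounts(w0, a0, cm$cmin, cm$cmax)
  expect_true(all(unlist(pa) == 0))

  w <- c(leaf = 100, stem = 0, so = 0, rt = 0)
  pa <- plantAmounts(w, a0, cm$cmin, cm$cmax)
  expect_equal(unname(pa$max), rep(4, 3))    # single organ, cmax 0.04
  expect_equal(unname(pa$min), rep(1, 3))
  expect_equal(unname(pa$opt), rep(1 + 0.8 * 3, 3))

  # Opt = Min + FR_MAX * (Max - Min) on arbitrary numbers
  cm2 <- flatConc(0.02, 0.10)
  pa2 <- plantAmounts(w, a0, cm2$cmin, cm2$cmax, fr_max = 0.8)
  expect_equal(unname(pa2$opt), rep(2 + 0.8 * (10 - 2), 3))
  expect_error(plantAmounts(c(leaf = -1, stem = 0, so = 0, rt = 0),
                            a0, cm$cmin, cm$cmax))
})

test_that("nutrient-equivalent demand and supply follow the conversion rule", {
  mx <- c(N = 10, P = 1, K = 8)
  expect_equal(nutrientEquivalentDemand(c(N = 6, P = 0.6, K = 4), mx), 13)
  expect_equal(nutrientEquivalentDemand(mx, mx), 0)
  expect_equal(nutrientEquivalentDemand(c(N = 10, P = 1, K = 4), mx), 5)
  # zero maxima contribute nothing rather than dividing by zero
  expect_equal(nutrientEquivalentDemand(c(N = 0, P = 0, K = 0),
                                        c(N = 0, P = 0, K = 0)), 0)

  a <- c(N = 2, P = 0.3, K = 4)
  expect_equal(nutrientEquivalentSupply(a, mx), 10)
  expect_equal(nutrientEquivalentSupply(2 * a, mx),
               2 * nutrientEquivalentSupply(a, mx))   # homogeneity
  expect_equal(nutrientEquivalentSupply(c(N = 0, P = 0, K = 0), mx), 0)
})

test_that("uptake is limited by equivalents, own demand and the soil pool", {
  p <- defaultParameters()
  mx <- c(N = 10, P = 1, K = 8)
  act <- c(N = 6, P = 0.6, K = 4)
  a <- c(N = 50, P = 50, K = 50)
  out <- uptakeRates(ned = 13, nes = 10, act, mx, a, p)
  expect_equal(out$dneup, 0.012 * 10)
  expect_true(all(out$up >= 0))
  expect_equal(unname(out$up), unname(pmin(mx - act, mx / mx[["N"]] * out$dneup)))

  a_k0 <- c(N = 50, P = 50, K = 0)
  expect_equal(uptakeRates(13, 10, act, mx, a_k0, p)$up[["K"]], 0)
  sat <- c(N = 10, P = 0.6, K = 4)   # N demand met
  expect_equal(uptakeRates(5, 100, sat, mx, a, p)$up[["N"]], 0)
})

test_that("uptake allocation is proportional to organ biomass and exact", {
  up <- c(N = 1, P = 0.2, K = 0.8)
  eq <- allocateUptake(up, c(leaf = 5, stem = 5, so = 5, rt = 5))
  expect_equal(unname(eq[, "N"]), rep(0.25, 4))
  sh <- allocateUptake(up, c(leaf = 100, stem = 50, so = 50, rt = 0))
  expect_equal(unname(sh[, "K"]), 0.8 * c(0.5, 0.25, 0.25, 0))
  expect_equal(colSums(sh), up)
  one <- allocateUptake(up, c(leaf = 0, stem = 0, so = 7, rt = 0))
  expect_equal(one["so", ], up)
  expect_warning(allocateUptake(up, c(leaf = 0, stem = 0, so = 0, rt = 0)),
                 "biomass")
})

test_that("redistribution relaxes towards equal saturation and conserves", {
  organs <- c("leaf", "stem", "so", "rt")
  nutrients <- c("N", "P", "K")
  amounts <- matrix(0, 4, 3, dimnames = list(organs, nutrients))
  amounts["leaf", "N"] <- 8
  amounts["stem", "N"] <- 2
  contrib <- matrix(0, 4, 3, dimnames = list(organs, nutrients))
  contrib[c("leaf", "stem"), "N"] <- 1   # equal max shares -> target (5, 5)
  r <- redistributionRates(amounts, contrib, tc = 10)
  expect_equal(r["leaf", "N"], -0.3)
  expect_equal(r["stem", "N"], 0.3)

  # already proportional: no transfers
  prop <- contrib * 4
  r0 <- redistributionRates(prop, contrib, tc = 10)
  expect_true(all(abs(r0) < 1e-12))

  set.seed(11)
  for (i in 1:20) {
    am <- matrix(runif(12), 4, 3, dimnames = list(organs, nutrients))
    cb <- matrix(runif(12), 4, 3, dimnames = list(organs, nutrients))
    expect_equal(unname(colSums(redistributionRates(am, cb, 10))),
                 c(0, 0, 0), tolerance = 1e-12)
  }
})

test_that("dying leaves hand N to stems and P, K to storage organs", {
  organs <- c("leaf", "stem", "so", "rt")
  amounts <- matrix(0, 4, 3, dimnames = list(organs, c("N", "P", "K")))
  amounts["leaf", ] <- c(10, 1, 5)
  tr <- rerouteDeadLeafNutrients(0.1, amounts)   # 10% of the canopy dies
  expect_equal(tr["stem", "N"], 1.0)
  expect_equal(tr["so", "P"], 0.1)
  expect_equal(tr["so", "K"], 0.5)
  expect_equal(tr["leaf", ], -c(N = 1.0, P = 0.1, K = 0.5))
  expect_equal(unname(colSums(tr)), c(0, 0, 0))  # whole plant unchanged
  none <- rerouteDeadLeafNutrients(0, amounts)
  expect_true(all(none == 0))
  expect_error(rerouteDeadLeafNutrients(1.5, amounts))
})

test_that("the combined index matches the published transform", {
  expect_equal(round(npki(0.8, 6.1, 4), 2), 0.77)
  expect_equal(npki(0.8, 6.1, 4), 1 - 7.1 * 0.2 / 6.3, tolerance = 1e-12)
  # no stress maps to exactly 1 on either branch, for any K_NI
  for (k in c(0.5, 2, 4, 6.1, 42)) {
    expect_identical(npki(1, k, 4), 1)
    expect_identical(npki(1, k, 100), 1)
  }
  # saturating branch below KMAX
  expect_equal(npki(0.5, 2, 4), 3 * 0.5 / 2.5, tolerance = 1e-12)
  # monotone non-decreasing in the product on both branches
  pr <- seq(0, 1, by = 0.01)
  expect_true(all(diff(npki(pr, 6.1, 4)) >= 0))
  expect_true(all(diff(npki(pr, 2, 4)) >= 0))
  expect_true(all(npki(pr, 6.1, 4) >= 0 & npki(pr, 6.1, 4) <= 1))
  expect_error(npki(1.2))
})

test_that("nutrition indices clamp, gate on thermal time and degenerate safely", {
  p <- defaultParameters()
  mk <- function(act) nutritionIndices(
    act = c(N = act, P = 8, K = 8), min = c(N = 2, P = 2, K = 2),
    opt = c(N = 8, P = 8, K = 8), tsum = 1000, params = p)
  expect_equal(mk(5)$ni[["N"]], 0.5)
  expect_equal(mk(20)$ni[["N"]], 1)      # luxury clamps at 1
  expect_equal(mk(0)$ni[["N"]], 0)
  # monotone in the actual amount
  ni_seq <- vapply(seq(0, 12, 0.5), function(a) mk(a)$ni[["N"]], numeric(1))
  expect_true(all(diff(ni_seq) >= 0))
  # gate: below TSUM_NPKI the combined index is 1 regardless of stress
  gated <- nutritionIndices(c(N = 0, P = 0, K = 0), c(N = 0, P = 0, K = 0),
                            c(N = 1, P = 1, K = 1), tsum = 100, params = p)
  expect_identical(gated$npki, 1)
  open <- nutritionIndices(c(N = 0, P = 0, K = 0), c(N = 0, P = 0, K = 0),
                           c(N = 1, P = 1, K = 1), tsum = 272, params = p)
  expect_lt(open$npki, 0.01)
  # degenerate span: at or above the minimum counts as replete
  deg <- nutritionIndices(c(N = 3, P = 3, K = 3), c(N = 3, P = 3, K = 3),
                          c(N = 3, P = 3, K = 3), tsum = 1000, params = p)
  expect_equal(unname(deg$ni), c(1, 1, 1))
})

test_that("potassium scarcity drags nitrogen uptake down with it", {
  p <- defaultParameters()
  wx <- wetWeather200()
  balanced <- cassavaScenario(siteSupply(20, 2, 10), weather = wx)
  no_k <- cassavaScenario(siteSupply(20, 2, 0), weather = wx)
  up_n <- function(sc) {
    s <- runSimulation(p, sc)
    attr(s, "soil_final")$cum_uptake[["N"]]
  }
  expect_lt(up_n(no_k), up_n(balanced))
})
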