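test_that("NBE is the exact sum of its components", {
  expect_equal(computeNBE(-89.3, 59.7, 0.4, 1.4), -27.8)
  expect_equal(computeNBE(0, 0), 0)
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(4, 0, 50)
    expect_equal(computeNBE(x[1], x[2], x[3], x[4]), sum(x),
                 tolerance = 1e-14)
  }
})

test_that("scenario runs are deterministic and respect protection masks", {
  ls <- tinyLandscape(seed = 6)
  cl <- standardClimate(2015:2034, seed = 6)
  sc <- harvestScenario("BaseHarv", 2015:2034, baseTargetOf(ls))
  a <- runScenario(ls, sc, cl)
  b <- runScenario(ls, sc, cl)
  expect_identical(a$fluxes, b$fluxes)
  expect_identical(a$finalStates, b$finalStates)

  # full protection mask turns every scenario into no-harvest
  grid <- gridGeometry(ls)
  allMask <- matrix(TRUE, grid@nrow, grid@ncol)
  m <- runScenario(ls, sc, cl, newProtectionMask = allMask)
  expect_true(all(m$fluxes$harvested_volume_m3 == 0))
  expect_error(runScenario(ls, sc, cl,
                           newProtectionMask = matrix(TRUE, 2, 2)),
               "mask geometry")
  expect_error(runScenario(ls, sc, cl, years = 2000:2010), "coverage")
})

test_that("warming climate strengthens the simulated carbon sink", {
  ls <- tinyLandscape(seed = 8)
  yrs <- 2015:2050
  sc <- harvestScenario("BaseHarv", yrs, baseTargetOf(ls))
  cur <- runScenario(ls, sc, standardClimate(yrs, 8, "current"))
  wrm <- runScenario(ls, sc, standardClimate(yrs, 8, "warming"))
  expect_lt(mean(wrm$fluxes$nee_tg), mean(cur$fluxes$nee_tg))
})

test_that("aggregate NBE does not decrease with harvest intensity", {
  ls <- tinyLandscape(seed = 12)
  yrs <- 2015:2044
  cl <- standardClimate(yrs, 12)
  bt <- baseTargetOf(ls)
  nbe <- vapply(c("NoHarv", "LowHarv", "BaseHarv", "MaxHarv"), function(nm) {
    mean(runScenario(ls, harvestScenario(nm, yrs, bt), cl)$fluxes$nbe)
  }, numeric(1))
  expect_true(all(diff(nbe) >= -1e-12))
})

test_that("long no-harvest run approaches a storage equilibrium", {
  ls <- tinyLandscape(seed = 9, nrow = 12, ncol = 12)
  cl <- standardClimate(2015:2114, seed = 9)
  m <- maxStoragePotential(ls, cl, horizonYears = 100)
  tr <- m$trajectory$total_storage_tgc
  expect_equal(length(tr), 100)
  expect_gt(m$storage_tgc, 0)
  # decade increments shrink towards the horizon
  firstDecade <- tr[10] - tr[1]
  lastDecade <- tr[100] - tr[91]
  expect_lt(lastDecade, 0.5 * firstDecade)
  # near-equilibrium: annual litter approximately balances respiration
  f <- m$run$fluxes
  expect_equal(mean(utils::tail(f$rh, 5)), mean(utils::tail(f$litter, 5)),
               tolerance = 0.05)
  # horizon 0 returns current storage with no trajectory
  cur <- maxStoragePotential(ls, cl, 0)
  expect_equal(cur$storage_tgc,
               runScenario(ls, harvestScenario("NoHarv", 2015, 0),
                           cl, 2015)$fluxes$total_storage_tgc[1],
               tolerance = 0.15)
  expect_equal(nrow(cur$trajectory), 0)
})
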