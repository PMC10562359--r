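test_that("gas conversion is linear with exact CO2 identity", {
  expect_equal(co2eq(1, "CO2"), 1)
  expect_equal(co2eq(1, "CH4"), 25)
  expect_equal(co2eq(2, "N2O", c(CO2 = 1, CH4 = 28, N2O = 265)), 530)
  set.seed(3)
  m <- stats::runif(9)
  g <- sample(c("CO2", "CH4", "N2O"), 9, replace = TRUE)
  expect_equal(sum(co2eq(m, g)), sum(vapply(seq_len(9), function(i)
    co2eq(m[i], g[i]), numeric(1))))
  expect_error(co2eq(1, "SF6"), "unknown gas")
})

test_that("budget table computes nets and totals from components", {
  bt <- budgetData(buildBudgetTable(landUseReference()))
  forests <- bt[bt$land_use == "forests", ]
  expect_equal(forests$net, -27.7)
  expect_equal(bt$net[bt$land_use == "total"], 54.0)
  expect_equal(bt$area_pct[bt$land_use == "total"], 100)

  # all-zero input gives an all-zero table
  zero <- data.frame(land_use = c("a", "b"), area_km2 = c(1, 1),
                     emissions = 0, sinks = 0)
  bz <- budgetData(buildBudgetTable(zero))
  expect_true(all(bz[, c("emissions", "sinks", "net", "c_storage")] == 0))

  expect_error(buildBudgetTable(data.frame(land_use = "x", emissions = 1)),
               "missing")
  # inconsistent tables cannot be constructed directly either
  bad <- bt; bad$net[1] <- 99
  expect_error(new("BudgetTable", data = bad), "net must equal")
})

test_that("regional nets sum to the national net", {
  f <- data.frame(region_id = 1:3, nbe = c(-5, 2, -1))
  a <- data.frame(region_id = 1:3, emission = c(3, 1, 4))
  net <- regionalNetEmissions(f, a)
  expect_equal(net$net, c(-2, 3, 3))
  expect_equal(sum(net$net), sum(f$nbe) + sum(a$emission))
  expect_error(regionalNetEmissions(f, a[1:2, ]), "region sets")
})

test_that("harvest intensity increases the count of source regions", {
  ls <- tinyLandscape(seed = 25, nRegions = 6, nrow = 20, ncol = 20)
  yrs <- 2015:2035
  cl <- standardClimate(yrs, 25)
  bt <- baseTargetOf(ls)
  anthro <- data.frame(region_id = 1:6, emission = 0)
  nPositive <- vapply(c("LowHarv", "MaxHarv"), function(nm) {
    r <- runScenario(ls, harvestScenario(nm, yrs, bt), cl)
    rf <- r$regionFluxes
    f <- stats::aggregate(nbe ~ region_id, rf[rf$year >= 2026, ], mean)
    sum(regionalNetEmissions(f, anthro)$net > 0)
  }, numeric(1))
  expect_gt(nPositive[["MaxHarv"]], nPositive[["LowHarv"]])
})

test_that("ensembles are reproducible with degenerate and stochastic draws", {
  # point-mass distributions give a zero-width interval
  ens0 <- runEnsemble(function(p, s) p$x,
                      list(x = list(dist = "point", value = 3)), n = 10,
                      seed = 1)
  s0 <- ensembleSummary(ens0)
  expect_equal(s0$lower, s0$upper)
  expect_equal(s0$mean, 3)

  a <- runEnsemble(function(p, s) p$x + p$y,
                   list(x = list(dist = "normal", mean = 1, sd = 2),
                        y = list(dist = "uniform", min = 0, max = 1)),
                   n = 50, seed = 9)
  b <- runEnsemble(function(p, s) p$x + p$y,
                   list(x = list(dist = "normal", mean = 1, sd = 2),
                        y = list(dist = "uniform", min = 0, max = 1)),
                   n = 50, seed = 9)
  expect_identical(ensembleSamples(a), ensembleSamples(b))

  # failed draws are excluded and counted
  ens <- runEnsemble(function(p, s) if (p$x > 0) p$x else stop("neg"),
                     list(x = list(dist = "normal", mean = 0, sd = 1)),
                     n = 40, seed = 2)
  expect_gt(ens@nFailed, 0)
  expect_equal(length(ensembleSamples(ens)) + ens@nFailed, 40)
  expect_error(runEnsemble(function(p, s) 1, list(), n = 1), "n must be")
})

test_that("neutrality probability behaves at the boundaries", {
  expect_equal(neutralityProbability(rep(-50, 10), rep(20, 10)), 1)
  expect_equal(neutralityProbability(rep(50, 10), rep(20, 10)), 0)
  set.seed(10)
  sym <- stats::rnorm(2e4)
  expect_equal(neutralityProbability(sym, rep(0, 5)), 0.5, tolerance = 0.02)
  expect_error(neutralityProbability(numeric(0), 1), "empty")
  # monotone non-increasing in added anthropogenic emissions
  f <- stats::rnorm(5000, -10, 5)
  p1 <- neutralityProbability(f, stats::rnorm(5000, 5, 2))
  p2 <- neutralityProbability(f, stats::rnorm(5000, 15, 2))
  expect_gte(p1, p2)
})

test_that("service accounts scale with scope and valuation is exact", {
  expect_equal(economicValue(4500, 70), 4500 * 44 / 12 * 70)
  expect_equal(economicValue(0, 70), 0)
  expect_error(economicValue(-1), "storage")

  ls <- tinyLandscape(seed = 15)
  yrs <- 2015:2040
  cl <- standardClimate(yrs, 15)
  run <- runScenario(ls, harvestScenario("NoHarv", yrs, baseTargetOf(ls)),
                     cl)
  grid <- gridGeometry(ls)
  empty <- matrix(FALSE, grid@nrow, grid@ncol)
  sEmpty <- climateServices(run, ls, empty, scope = "currently_protected")
  expect_equal(sEmpty@cStorage, 0)
  expect_equal(sEmpty@economicValue, 0)

  whole <- climateServices(run, ls, NULL, scope = "whole_region")
  lastStore <- run$fluxes$total_storage_tgc[nrow(run$fluxes)]
  expect_equal(whole@cStorage, lastStore, tolerance = 1e-9)
  expect_equal(whole@economicValue, economicValue(lastStore, 70))

  # larger protection scope stores more carbon
  cur <- protectedMask(ls)
  fs <- generateBdFeatures(ls, 4, seed = 15)
  rk <- rankCells(fs, "ABF", protectedMask = cur, warp = 2)
  sel <- selectProtectionAreas(rk, ls, 0.10)
  sCur <- climateServices(run, ls, cur, scope = "currently_protected")
  sTgt <- climateServices(run, ls, cur | sel$mask, scope = "target_10pct")
  expect_gt(sTgt@cStorage, sCur@cStorage)
  # soil truncation reduces the counted storage
  sHalf <- climateServices(run, ls, NULL, soilTruncationFraction = 0.5)
  expect_lt(sHalf@cStorage, whole@cStorage)
})
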