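test_that("area allocation conserves totals and follows the proxy", {
  uni <- matrix(1, 2, 2)
  tot <- data.frame(sector = "traffic_exhaust", gas = "CO2", total = 10)
  g <- allocateAreaSources(tot, list(traffic_exhaust = uni))
  expect_equal(as.vector(g[["traffic_exhaust|CO2"]]), rep(2.5, 4))

  # proxy permutation permutes cells but leaves the total invariant
  set.seed(17)
  proxy <- matrix(stats::runif(36), 6, 6)
  g1 <- allocateAreaSources(tot, list(traffic_exhaust = proxy))
  perm <- matrix(sample(as.vector(proxy)), 6, 6)
  g2 <- allocateAreaSources(tot, list(traffic_exhaust = perm))
  expect_equal(sum(g1[[1]]), sum(g2[[1]]))
  expect_setequal(round(as.vector(g1[[1]]), 12), round(as.vector(g2[[1]]), 12))

  # zero-proxy cells stay zero; all-zero proxy with mass is an error
  proxy0 <- proxy; proxy0[1, ] <- 0
  g3 <- allocateAreaSources(tot, list(traffic_exhaust = proxy0))
  expect_true(all(g3[[1]][1, ] == 0))
  expect_error(allocateAreaSources(tot,
                                   list(traffic_exhaust = matrix(0, 2, 2))),
               "all-zero proxy")
  expect_error(allocateAreaSources(data.frame(sector = "s", gas = "CO2",
                                              total = -1),
                                   list(s = uni)), ">= 0")
})

test_that("generated inventory reproduces the configured national total", {
  ls <- tinyLandscape(seed = 5)
  inv <- generateEmissionInventory(ls, emissionConfig(), seed = 5)
  expect_equal(nationalTotal(inv), 54.1, tolerance = 1e-10)
  # all six area-source sectors present on the grid
  gridSectors <- unique(sub("\\|.*$", "", names(areaSources(inv))))
  expect_setequal(gridSectors,
                  c("traffic_exhaust", "machinery_offroad",
                    "wood_combustion", "other_small_combustion",
                    "agriculture", "waste_management"))
  # zero point share puts everything on the grid
  cfg <- emissionConfig()
  sh <- cfg$sectorShares
  sh$share[sh$type == "point"] <- 0
  sh$share <- sh$share / sum(sh$share)
  inv2 <- generateEmissionInventory(ls, emissionConfig(sectorShares = sh),
                                    seed = 5)
  expect_equal(sum(pointSources(inv2)$emission), 0)
  expect_equal(sum(vapply(areaSources(inv2), sum, numeric(1))), 54.1,
               tolerance = 1e-10)
  expect_error(emissionConfig(nationalTotal = -5), ">= 0")
})

test_that("scenario scaling reproduces anchors, identity and linearity", {
  ls <- tinyLandscape(seed = 5)
  inv <- generateEmissionInventory(ls, emissionConfig(), seed = 5)
  wem <- scenarioTrajectory("WEM")
  wam <- scenarioTrajectory("WAM")
  wamNo <- scenarioTrajectory("WAM", ccsFlag = FALSE)

  expect_equal(nationalTotal(scaleToScenario(inv, wem, 2019)), 54.1,
               tolerance = 1e-10)
  expect_equal(nationalTotal(scaleToScenario(inv, wem, 2030)), 39.0,
               tolerance = 1e-10)
  expect_equal(nationalTotal(scaleToScenario(inv, wem, 2050)), 22.9,
               tolerance = 1e-10)
  expect_equal(nationalTotal(scaleToScenario(inv, wam, 2030)), 33.4,
               tolerance = 1e-10)
  expect_equal(nationalTotal(scaleToScenario(inv, wam, 2050)), 8.6,
               tolerance = 1e-10)
  expect_equal(nationalTotal(scaleToScenario(inv, wamNo, 2050)), 17.6,
               tolerance = 1e-10)

  # identity at the base year: inventory unchanged
  s0 <- scaleToScenario(inv, wem, 2019)
  expect_equal(pointSources(s0)$emission, pointSources(inv)$emission)
  expect_equal(areaSources(s0), areaSources(inv))

  # linearity: scaling a doubled inventory doubles the scaled result
  inv2 <- generateEmissionInventory(ls, emissionConfig(nationalTotal = 108.2),
                                    seed = 5)
  expect_equal(nationalTotal(scaleToScenario(inv2, wem, 2030)),
               2 * nationalTotal(scaleToScenario(inv, wem, 2030)),
               tolerance = 1e-9)
  expect_error(scaleToScenario(inv, wem, 2060), "span")
})

test_that("regional WAM output after 2030 is refused under the CCS assumption", {
  ls <- tinyLandscape(seed = 5)
  inv <- generateEmissionInventory(ls, emissionConfig(), seed = 5)
  wam <- scenarioTrajectory("WAM")
  s <- scaleToScenario(inv, wam, 2050)
  expect_false(s@spatialValid)
  expect_error(aggregateInventoryToRegions(s), "national")
  # at 2030 the WAM result is still spatial
  expect_true(scaleToScenario(inv, wam, 2030)@spatialValid)
})

test_that("regional aggregation conserves the national total and refines", {
  ls <- tinyLandscape(seed = 5, nRegions = 4)
  inv <- generateEmissionInventory(ls, emissionConfig(), seed = 5)
  d <- aggregateInventoryToRegions(inv)
  expect_equal(sum(d$emission), nationalTotal(inv), tolerance = 1e-9)

  # one region: regional total equals the national total
  ls1 <- tinyLandscape(seed = 5, nRegions = 1)
  inv1 <- generateEmissionInventory(ls1, emissionConfig(), seed = 5)
  rt <- regionalInventoryTotals(inv1)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$emission, nationalTotal(inv1), tolerance = 1e-10)

  # refinement invariance: splitting a region leaves the subtotal the sum
  invSplit <- inv
  rm2 <- invSplit@regionMap
  target <- rm2 == 1
  half <- target & (col(rm2) > ncol(rm2) / 2)
  rm2[half] <- 99L
  invSplit@regionMap <- rm2
  before <- regionalInventoryTotals(inv)
  after <- regionalInventoryTotals(invSplit)
  expect_equal(sum(after$emission[after$region_id %in% c(1, 99)]),
               before$emission[before$region_id == 1], tolerance = 1e-9)
})

test_that("inventory uncertainty sampling matches configured intervals", {
  # zero-width interval: point mass
  s0 <- sampleInventoryUncertainty(
    data.frame(sector = "a", mean = 5, lower = 5, upper = 5), 100, 1)
  expect_true(all(s0 == 5))

  # two independent sectors: variances add
  iv2 <- data.frame(sector = c("a", "b"), mean = c(10, 20),
                    lower = c(8, 15), upper = c(13, 24))
  s2 <- sampleInventoryUncertainty(iv2, 2e5, 2)
  sa <- sampleInventoryUncertainty(iv2[1, ], 2e5, 3)
  sb <- sampleInventoryUncertainty(iv2[2, ], 2e5, 4)
  expect_equal(stats::var(s2), stats::var(sa) + stats::var(sb),
               tolerance = 0.03)
  expect_error(sampleInventoryUncertainty(
    data.frame(sector = "a", mean = 5, lower = 6, upper = 7), 10, 1),
    "bracket")
})
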