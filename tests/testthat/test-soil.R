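test_that("soil pool cascade matches its discrete definition", {
  # single pool, k = 0.1, mass 100, g = 1, no transfer: rh = 10
  p <- forestParams(soilK = c(one = 0.1), soilTransfer = 0)
  st <- soilStep(matrix(100), 0, temperature = p$soilTRef, p)
  expect_equal(st$rh, 10)
  expect_equal(as.numeric(st$pools), 90)

  # zero decay: no respiration, litter accumulates in the first pool
  p0 <- forestParams(soilK = c(a = 0, b = 0, c = 0),
                     soilTransfer = c(0, 0, 0))
  st0 <- soilStep(matrix(c(5, 5, 5), 1), 3, 10, p0)
  expect_equal(st0$rh, 0)
  expect_equal(as.numeric(st0$pools), c(8, 5, 5))

  # decay modifier increases with temperature
  p3 <- forestParams()
  rhCold <- soilStep(matrix(c(10, 30, 50), 1), 0, 0, p3)$rh
  rhWarm <- soilStep(matrix(c(10, 30, 50), 1), 0, 10, p3)$rh
  expect_gt(rhWarm, rhCold)

  # decay fraction capped: pools can never go negative
  pBig <- forestParams(soilK = c(a = 50, b = 50, c = 50))
  stBig <- soilStep(matrix(c(1, 1, 1), 1), 0, 30, pBig)
  expect_true(all(stBig$pools >= 0))
  expect_error(soilStep(matrix(1), -1, 5), "litterInput")
})

test_that("soil carbon is conserved over a 50-year ledger replay", {
  p <- forestParams()
  set.seed(14)
  pools <- matrix(c(4, 20, 45), 1)
  total0 <- sum(pools)
  litterSum <- 0
  rhSum <- 0
  for (i in 1:50) {
    litter <- stats::runif(1, 0, 6)
    temp <- stats::runif(1, -2, 10)
    st <- soilStep(pools, litter, temp, p)
    pools <- st$pools
    litterSum <- litterSum + litter
    rhSum <- rhSum + st$rh
  }
  closure <- abs((sum(pools) - total0) - (litterSum - rhSum))
  expect_lt(closure / sum(pools), 1e-9)
})

test_that("drained-peat coefficients follow the fertility sign convention", {
  rich <- peatSoilFlux("nutrient_rich_peat", 1e6)
  poor <- peatSoilFlux("nutrient_poor_peat", 1e6)
  expect_gt(rich$co2_soil, 0)    # nutrient-rich: source
  expect_lt(poor$co2_soil, 0)    # nutrient-poor: small sink
  expect_lt(abs(poor$co2_soil), rich$co2_soil)
  expect_gt(rich$ch4, 0)
  expect_gt(rich$n2o, poor$n2o)

  zero <- peatSoilFlux("nutrient_rich_peat", 0)
  expect_equal(unlist(zero), c(co2_soil = 0, ch4 = 0, n2o = 0))
  expect_error(peatSoilFlux("mesic", 1e4), "drained peat")
})
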