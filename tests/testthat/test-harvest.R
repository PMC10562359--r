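test_that("harvest scenarios carry the fixed intensity multipliers", {
  yrs <- 2015:2030
  base <- harvestScenario("BaseHarv", yrs, 80)
  low <- harvestScenario("LowHarv", yrs, 80)
  max_ <- harvestScenario("MaxHarv", yrs, 80)
  no <- harvestScenario("NoHarv", yrs, 80)
  # historical window uses realised removals for every scenario
  expect_equal(unname(low@targets["2020"]), 80)
  expect_equal(unname(no@targets["2020"]), 80)
  # after 2021: 0.6x / 1.2x / 0
  expect_equal(unname(base@targets["2025"]), 80)
  expect_equal(unname(low@targets["2025"]), 48)
  expect_equal(unname(max_@targets["2025"]), 96)
  expect_equal(unname(no@targets["2025"]), 0)
  expect_error(new("HarvestScenario", name = "LowHarv",
                   intensityMultiplier = 0.9, targets = c(`2020` = 1)),
               "does not match")
})

test_that("harvest allocation hits feasible targets exactly and spares protected land", {
  states <- data.frame(
    segment_id = 1:6, area_m2 = rep(1e4, 6),       # 1 ha each
    stem_volume = c(200, 150, 120, 300, 250, 80),
    age = c(90, 85, 40, 95, 88, 30),
    management_class = c("productive", "productive", "productive",
                         "protected", "poorly_productive", "productive"),
    eligible = TRUE)
  p <- forestParams(residueFraction = 0.3, clearcutAge = 80,
                    thinFraction = 0.3)
  sc <- harvestScenario("BaseHarv", 2025, 100)
  hv <- applyHarvest(states, sc, 2025, p)
  expect_equal(hv$totalRemovedM3, 100)
  expect_false(hv$infeasible)
  # protected and poorly productive untouched despite being oldest/largest
  expect_equal(hv$removedVolumeM3[4:5], c(0, 0))
  # oldest productive stand is taken first
  expect_gt(hv$removedVolumeM3[1], 0)
  # residue litter is the configured share of removed biomass
  expect_equal(hv$residueLitter, 0.3 * hv$removedBiomass)

  # all-protected landscape yields nothing, flagged infeasible
  states2 <- states
  states2$management_class <- "protected"
  hv2 <- applyHarvest(states2, sc, 2025, p)
  expect_equal(hv2$totalRemovedM3, 0)
  expect_true(hv2$infeasible)

  # infeasible target removes everything removable and reports it
  scBig <- harvestScenario("BaseHarv", 2025, 1e6)
  hv3 <- applyHarvest(states, scBig, 2025, p)
  expect_true(hv3$infeasible)
  expect_lt(hv3$totalRemovedM3, 1e6)
  expect_error(applyHarvest(states, sc, 1999, p), "no harvest target")
})

test_that("volume-carbon conversion matches the fixed density and round-trips", {
  expect_equal(harvestVolumeToCarbon(81.5), 81.5 * 0.2 * 44 / 12)
  expect_equal(harvestVolumeToCarbon(81.5), 59.8, tolerance = 1e-3)
  expect_equal(harvestVolumeToCarbon(0), 0)
  v <- c(0, 1.7, 81.5, 300)
  expect_equal(carbonToHarvestVolume(harvestVolumeToCarbon(v)), v)
  expect_error(harvestVolumeToCarbon(-1), "volume")
})
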