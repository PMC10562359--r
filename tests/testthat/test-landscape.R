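test_that("generated landscape matches configured structure", {
  ls <- tinyLandscape(seed = 11, nRegions = 5, nrow = 24, ncol = 24)
  rg <- regionTable(ls)
  seg <- segmentTable(ls)

  # regions partition the grid and areas are consistent
  expect_equal(nrow(rg), 5)
  expect_false(anyNA(regionMap(ls)))
  expect_equal(sum(rg$land_area_km2), 24 * 24 * 96^2 / 1e6)

  # segment areas sum exactly to each region's forest area
  segArea <- tapply(seg$area_m2, seg$region_id, sum) / 1e6
  expect_equal(as.numeric(segArea[as.character(rg$region_id)]),
               rg$forest_area_km2, tolerance = 1e-3)

  # forest share close to the configured 69%
  share <- sum(rg$forest_area_km2) / sum(rg$land_area_km2)
  expect_gt(share, 0.65)
  expect_lt(share, 0.73)

  # attribute mixtures within sampling error of configured proportions
  n <- nrow(seg)
  pPine <- mean(seg$species == "pine")
  expect_lt(abs(pPine - 0.5), 4 * sqrt(0.25 / n))
  pPeat <- mean(seg$soil == "drained_peat")
  expect_lt(abs(pPeat - 0.25), 4 * sqrt(0.25 * 0.75 / n))

  # drained peat always carries a peat fertility class
  expect_true(all(seg$site_fertility[seg$soil == "drained_peat"] %in%
                    c("nutrient_rich_peat", "nutrient_poor_peat")))
})

test_that("degenerate configs behave as specified", {
  # fully protected single region
  ls <- tinyLandscape(seed = 2, nRegions = 1, nrow = 10, ncol = 10,
                      protectedFraction = 1.0)
  expect_true(all(segmentTable(ls)$management_class == "protected"))
  expect_equal(regionTable(ls)$protected_fraction, 1.0)

  # invalid proportions rejected
  expect_error(landscapeConfig(forestFraction = 1.2), "forestFraction")
  expect_error(landscapeConfig(speciesMix = c(pine = 0.7, spruce = 0.7,
                                              broadleaf = 0.1)),
               "sum to 1")
  expect_error(landscapeConfig(notAKey = 1), "unknown")
})

test_that("identical seed and config give byte-identical landscapes", {
  a <- tinyLandscape(seed = 42, nRegions = 4)
  b <- tinyLandscape(seed = 42, nRegions = 4)
  expect_identical(segmentTable(a), segmentTable(b))
  expect_identical(regionTable(a), regionTable(b))
  expect_identical(regionMap(a), regionMap(b))
  c <- tinyLandscape(seed = 43, nRegions = 4)
  expect_false(identical(segmentTable(a), segmentTable(c)))
})
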