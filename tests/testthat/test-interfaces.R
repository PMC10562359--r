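test_that("ascii-grid rasters round-trip and reject geometry mismatches", {
  grid <- gridGeom(5, 7, 96)
  m <- matrix(sample(0:5, 35, replace = TRUE), 5, 7)
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(m, path, grid)
  back <- readAsciiGrid(path, expectedGrid = grid)
  expect_identical(back$values, m + 0)          # integer layers exact
  expect_true(sameGrid(back$grid, grid))

  cont <- matrix(stats::rnorm(35), 5, 7)
  writeAsciiGrid(cont, path, grid)
  expect_equal(readAsciiGrid(path)$values, cont, tolerance = 1e-12)

  expect_error(writeAsciiGrid(matrix(0, 3, 3), path, grid), "3 x 3")
  other <- gridGeom(4, 4, 250)
  err <- tryCatch(readAsciiGrid(path, expectedGrid = other),
                  error = conditionMessage)
  expect_match(err, "5x7")
  expect_match(err, "4x4")
})

test_that("CSV round-trips and rejects comma-decimal dialects", {
  d <- data.frame(id = 1:3, name = c("a", "b", "c"),
                  x = c(1.5, -2.25, 0.125))
  path <- withr::local_tempfile(fileext = ".csv")
  writeTableCsv(d, path)
  back <- readTableCsv(path)
  expect_identical(names(back), names(d))
  expect_equal(back, d)

  writeLines(c("id;x", "1;\"2,5\""), path)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x", "1,\"2,5\"", "2,\"3,5\""), bad)
  expect_error(readTableCsv(bad), "comma decimal")
})

test_that("configs merge strictly and round-trip through YAML", {
  cfg <- runConfig(seed = 7, landscape = list(nRegions = 3))
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$landscape$nRegions, 3)
  expect_error(runConfig(unknownKey = 1), "unknown")
  expect_error(runConfig(landscape = list(bogus = 2)), "unknown")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeRunConfig(list(seed = 12, yearEnd = 2040), path)
  cfg2 <- readRunConfig(path)
  expect_equal(cfg2$seed, 12)
  expect_equal(cfg2$yearEnd, 2040)
})

test_that("seed streams are deterministic, distinct and in integer range", {
  expect_identical(seedStream(1, "landscape"), seedStream(1, "landscape"))
  expect_false(seedStream(1, "landscape") == seedStream(1, "climate"))
  expect_false(seedStream(1, "ensemble", 1) == seedStream(1, "ensemble", 2))
  for (s in c(0, 1, 2^28, 2^31 - 1))
    expect_lt(seedStream(s, "x"), 2^31)
})

test_that("the pipeline is deterministic and writes consistent outputs", {
  cfg <- function(dir) runConfig(
    seed = 5, outputDir = dir,
    yearStart = 2015L, yearEnd = 2040L,
    climates = "current",
    harvestScenarios = c("BaseHarv", "NoHarv"),
    landscape = list(gridNrow = 16, gridNcol = 16, nRegions = 3),
    prioritization = list(warp = 4L),
    accounting = list(ensembleN = 4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- runPipeline(cfg(d1))
  r2 <- runPipeline(cfg(d2))

  files <- c("segments.csv", "budget_table.csv", "protection_summary.csv",
             "neutrality_probability.csv", "regional_net_emissions.csv",
             "rank.asc")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), info = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  meta <- jsonlite::read_json(file.path(d1, "metadata.json"))
  expect_equal(meta$seed, 5)
  expect_identical(meta$config_hash,
                   jsonlite::read_json(
                     file.path(d2, "metadata.json"))$config_hash)
  expect_false(file.exists(file.path(d1, "FAILED")))
})

test_that("a failing stage leaves a marker and names the stage", {
  d <- withr::local_tempdir()
  cfg <- runConfig(seed = 2, outputDir = d,
                   climates = "current",
                   harvestScenarios = "NoHarv",
                   yearStart = 2015L, yearEnd = 2020L,
                   landscape = list(gridNrow = 8, gridNcol = 8,
                                    nRegions = 2),
                   prioritization = list(rule = "BOGUS"))
  expect_error(runPipeline(cfg), "prioritization")
  expect_true(file.exists(file.path(d, "FAILED")))
})
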