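#' @import methods
NULL

setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' GridGeometry: shared raster geometry
#'
#' Minimal raster geometry used by every gridded object in the package:
#' row-major cell layout, origin at the upper-left corner, square cells with
#' size in metres, 0-based cell ids counted along rows.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot cellsize numeric, cell edge length in metres.
#' @slot origin numeric length 2, (x, y) of the upper-left corner in metres.
#'
#' @exportClass GridGeometry
setClass("GridGeometry",
  representation(nrow = "integer", ncol = "integer",
                 cellsize = "numeric", origin = "numeric"),
  prototype(nrow = 1L, ncol = 1L, cellsize = 96, origin = c(0, 0)))

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || object@nrow < 1L)
    msg <- c(msg, "nrow must be a single positive integer")
  if (length(object@ncol) != 1L || object@ncol < 1L)
    msg <- c(msg, "ncol must be a single positive integer")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite numbers")
  if (length(msg)) msg else TRUE
})

#' Landscape: regions, forest segments and protection status
#'
#' The synthetic (or user-supplied) study area. Regions partition the master
#' grid; forest segments are sub-cell forest units carrying the attributes the
#' carbon simulator needs; the protected mask marks cells inside the existing
#' reserve network.
#'
#' @slot grid a [GridGeometry-class].
#' @slot regions data.frame with one row per region: \code{region_id},
#'   \code{name}, \code{land_area_km2}, \code{forest_area_km2},
#'   \code{protected_fraction}.
#' @slot segments data.frame with one row per forest segment: \code{segment_id},
#'   \code{region_id}, \code{cell_id} (0-based master-grid cell), \code{area_m2},
#'   \code{species}, \code{site_fertility}, \code{soil}, \code{age},
#'   \code{stem_volume} (m3/ha), \code{management_class},
#'   \code{years_since_action}, \code{mgmt_intensity}.
#' @slot regionMap integer matrix (nrow x ncol) of region ids per cell.
#' @slot protectedMask logical matrix, TRUE where the cell is protected.
#'
#' @exportClass Landscape
setClass("Landscape",
  representation(grid = "GridGeometry", regions = "data.frame",
                 segments = "data.frame", regionMap = "matrix",
                 protectedMask = "matrix"))

.speciesLevels  <- c("pine", "spruce", "broadleaf")
.fertilityLevels <- c("herb_rich", "mesic", "sub_xeric",
                      "nutrient_rich_peat", "nutrient_poor_peat")
.soilLevels     <- c("mineral", "drained_peat")
.mgmtLevels     <- c("protected", "productive", "poorly_productive")
.peatFertility  <- c("nutrient_rich_peat", "nutrient_poor_peat")

setValidity("Landscape", function(object) {
  msg <- character()
  rg <- object@regions; sg <- object@segments; g <- object@grid
  needR <- c("region_id", "name", "land_area_km2", "forest_area_km2",
             "protected_fraction")
  needS <- c("segment_id", "region_id", "cell_id", "area_m2", "species",
             "site_fertility", "soil", "age", "stem_volume",
             "management_class", "years_since_action", "mgmt_intensity")
  if (!all(needR %in% names(rg)))
    return(paste("regions lacks columns:",
                 paste(setdiff(needR, names(rg)), collapse = ", ")))
  if (!all(needS %in% names(sg)))
    return(paste("segments lacks columns:",
                 paste(setdiff(needS, names(sg)), collapse = ", ")))
  if (any(rg$land_area_km2 <= 0)) msg <- c(msg, "land_area must be > 0")
  if (any(rg$forest_area_km2 > rg$land_area_km2 + 1e-9))
    msg <- c(msg, "forest_area must not exceed land_area")
  if (any(rg$protected_fraction < 0 | rg$protected_fraction > 1))
    msg <- c(msg, "protected_fraction must lie in [0, 1]")
  if (any(sg$area_m2 <= 0)) msg <- c(msg, "segment areas must be > 0")
  if (any(sg$age < 0)) msg <- c(msg, "segment ages must be >= 0")
  if (any(sg$stem_volume < 0)) msg <- c(msg, "stem volumes must be >= 0")
  if (!all(sg$species %in% .speciesLevels))
    msg <- c(msg, "unknown species level")
  if (!all(sg$soil %in% .soilLevels)) msg <- c(msg, "unknown soil level")
  if (!all(sg$site_fertility %in% .fertilityLevels))
    msg <- c(msg, "unknown site_fertility level")
  peat <- sg$soil == "drained_peat"
  if (any(peat & !(sg$site_fertility %in% .peatFertility)))
    msg <- c(msg, "drained_peat segments must carry a peat fertility class")
  if (any(!peat & sg$site_fertility %in% .peatFertility))
    msg <- c(msg, "mineral segments must carry a mineral fertility class")
  if (!all(sg$management_class %in% .mgmtLevels))
    msg <- c(msg, "unknown management_class level")
  if (!identical(dim(object@regionMap), c(g@nrow, g@ncol)))
    msg <- c(msg, "regionMap dimensions must match the grid")
  if (!identical(dim(object@protectedMask), c(g@nrow, g@ncol)))
    msg <- c(msg, "protectedMask dimensions must match the grid")
  if (anyNA(object@regionMap))
    msg <- c(msg, "regionMap must assign every cell to a region (partition)")
  if (!all(object@regionMap %in% rg$region_id))
    msg <- c(msg, "regionMap refers to unknown region ids")
  if (!all(sg$region_id %in% rg$region_id))
    msg <- c(msg, "segments refer to unknown region ids")
  if (any(sg$cell_id < 0 | sg$cell_id >= g@nrow * g@ncol))
    msg <- c(msg, "segment cell ids outside the grid")
  if (length(msg)) msg else TRUE
})

#' ClimateSeries: annual climate drivers for one scenario
#'
#' Annual-resolution forcing for the forest simulator: mean temperature,
#' growing-season photosynthetically active radiation, precipitation, mean
#' vapour pressure deficit and ambient CO2.
#'
#' @slot data data.frame with columns \code{year}, \code{temperature} (degC),
#'   \code{radiation} (MJ m-2 a-1, PAR), \code{precipitation} (mm a-1),
#'   \code{vpd} (kPa), \code{co2} (ppm).
#' @slot scenario "current" or "warming".
#'
#' @exportClass ClimateSeries
setClass("ClimateSeries",
  representation(data = "data.frame", scenario = "character"))

setValidity("ClimateSeries", function(object) {
  msg <- character()
  need <- c("year", "temperature", "radiation", "precipitation", "vpd", "co2")
  if (!all(need %in% names(object@data)))
    return(paste("climate data lacks columns:",
                 paste(setdiff(need, names(object@data)), collapse = ", ")))
  if (any(object@data$co2 < 280)) msg <- c(msg, "co2 must be >= 280 ppm")
  if (any(object@data$radiation < 0)) msg <- c(msg, "radiation must be >= 0")
  if (!object@scenario %in% c("current", "warming"))
    msg <- c(msg, "scenario must be 'current' or 'warming'")
  if (length(msg)) msg else TRUE
})

#' FeatureStack: biodiversity feature layers on a shared grid
#'
#' A stack of non-negative raster layers (deadwood potential, old-growth
#' likelihood, red-list observation density, ...) used by the prioritization
#' algorithm, with per-feature weights.
#'
#' @slot grid a [GridGeometry-class]; all layers share it.
#' @slot features numeric array (nrow x ncol x n_features), finite and >= 0,
#'   with feature names on the third dimension.
#' @slot weights named positive numeric, one per feature.
#'
#' @exportClass FeatureStack
setClass("FeatureStack",
  representation(grid = "GridGeometry", features = "array",
                 weights = "numeric"))

setValidity("FeatureStack", function(object) {
  msg <- character()
  f <- object@features; g <- object@grid
  if (length(dim(f)) != 3L) return("features must be a 3-d array")
  if (dim(f)[1] != g@nrow || dim(f)[2] != g@ncol)
    msg <- c(msg, "feature layers must match the grid geometry")
  if (dim(f)[3] < 1L) msg <- c(msg, "at least one feature layer required")
  if (any(!is.finite(f)) || any(f < 0))
    msg <- c(msg, "feature values must be finite and >= 0")
  if (is.null(dimnames(f)[[3]])) msg <- c(msg, "feature layers must be named")
  if (length(object@weights) != dim(f)[3] || any(object@weights <= 0))
    msg <- c(msg, "weights must be positive, one per feature")
  if (length(msg)) msg else TRUE
})

#' EmissionInventory: anthropogenic point and area GHG sources
#'
#' Point sources (major facilities, per region) and gridded area sources
#' (six sectors on a coarse grid, default 250 m), by gas, in TgCO2eq per year.
#'
#' @slot grid the area-source [GridGeometry-class].
#' @slot pointSources data.frame: \code{source_id}, \code{region_id},
#'   \code{sector}, \code{gas}, \code{emission} (TgCO2eq a-1).
#' @slot areaSources named list of matrices, one per "sector|gas" pair.
#' @slot sectors character, the area-source sectors present.
#' @slot regionMap integer matrix assigning each area cell to a region by the
#'   cell-centre rule.
#' @slot baseYear integer inventory base year.
#' @slot scenario character scenario label ("base", "WEM", "WAM").
#' @slot year integer, the year the inventory currently represents.
#' @slot spatialValid logical; FALSE when only the national total is
#'   meaningful (WAM after 2030 under the CCS assumption) and any regional
#'   disaggregation must refuse.
#'
#' @exportClass EmissionInventory
setClass("EmissionInventory",
  representation(grid = "GridGeometry", pointSources = "data.frame",
                 areaSources = "list", sectors = "character",
                 regionMap = "matrix", baseYear = "integer",
                 scenario = "character", year = "integer",
                 spatialValid = "logical"),
  prototype(scenario = "base", spatialValid = TRUE))

.gasLevels <- c("CO2", "CH4", "N2O")

setValidity("EmissionInventory", function(object) {
  msg <- character()
  ps <- object@pointSources
  need <- c("source_id", "region_id", "sector", "gas", "emission")
  if (!all(need %in% names(ps)))
    return(paste("pointSources lacks columns:",
                 paste(setdiff(need, names(ps)), collapse = ", ")))
  if (any(ps$emission < 0)) msg <- c(msg, "point emissions must be >= 0")
  if (!all(ps$gas %in% .gasLevels)) msg <- c(msg, "unknown gas in pointSources")
  g <- object@grid
  for (nm in names(object@areaSources)) {
    m <- object@areaSources[[nm]]
    if (!identical(dim(m), c(g@nrow, g@ncol))) {
      msg <- c(msg, sprintf("area layer '%s' does not match the grid", nm))
    } else if (any(m < 0)) {
      msg <- c(msg, sprintf("area layer '%s' has negative emissions", nm))
    }
  }
  if (!identical(dim(object@regionMap), c(g@nrow, g@ncol)))
    msg <- c(msg, "regionMap dimensions must match the area grid")
  if (length(msg)) msg else TRUE
})

#' ScenarioTrajectory: national emission scenario anchors
#'
#' A national emission trajectory ("with existing measures" WEM or
#' "with additional measures" WAM) given as national totals at anchor years,
#' interpolated piecewise-linearly in between. For WAM the post-2040
#' carbon-capture assumption gives two 2050 totals; when \code{ccsFlag} is
#' TRUE the capture-inclusive total is used and spatial output is suppressed
#' after 2030.
#'
#' @slot name "WEM" or "WAM".
#' @slot anchorYears numeric anchor years.
#' @slot totals national totals (TgCO2eq a-1) at the anchors.
#' @slot totalsNoCCS anchor totals without the carbon-capture assumption
#'   (equal to \code{totals} for WEM).
#' @slot ccsFlag logical, whether the capture assumption applies.
#'
#' @exportClass ScenarioTrajectory
setClass("ScenarioTrajectory",
  representation(name = "character", anchorYears = "numeric",
                 totals = "numeric", totalsNoCCS = "numeric",
                 ccsFlag = "logical"))

setValidity("ScenarioTrajectory", function(object) {
  msg <- character()
  if (length(object@anchorYears) != length(object@totals) ||
      length(object@totals) != length(object@totalsNoCCS))
    msg <- c(msg, "anchorYears, totals and totalsNoCCS must have equal length")
  if (is.unsorted(object@anchorYears, strictly = TRUE))
    msg <- c(msg, "anchorYears must be strictly increasing")
  if (any(object@totals < 0) || any(object@totalsNoCCS < 0))
    msg <- c(msg, "totals must be >= 0")
  if (length(msg)) msg else TRUE
})

#' HarvestScenario: harvest-intensity scenario
#'
#' Yearly total removal targets (m3 a-1). The historical window (to 2021)
#' uses realised removals for every scenario; afterwards BaseHarv continues
#' current practice, LowHarv is 0.6x, MaxHarv 1.2x and NoHarv stops harvesting.
#'
#' @slot name one of "BaseHarv", "LowHarv", "MaxHarv", "NoHarv".
#' @slot intensityMultiplier 1.0, 0.6, 1.2 or 0.0.
#' @slot targets named numeric, removal target (m3) per simulation year.
#'
#' @exportClass HarvestScenario
setClass("HarvestScenario",
  representation(name = "character", intensityMultiplier = "numeric",
                 targets = "numeric"))

.harvestMultipliers <- c(BaseHarv = 1.0, LowHarv = 0.6,
                         MaxHarv = 1.2, NoHarv = 0.0)

setValidity("HarvestScenario", function(object) {
  msg <- character()
  if (!object@name %in% names(.harvestMultipliers))
    msg <- c(msg, "name must be BaseHarv, LowHarv, MaxHarv or NoHarv")
  else if (!isTRUE(all.equal(object@intensityMultiplier,
                             unname(.harvestMultipliers[object@name]))))
    msg <- c(msg, "intensityMultiplier does not match the scenario name")
  if (any(object@targets < 0)) msg <- c(msg, "targets must be >= 0")
  if (is.null(names(object@targets)) && length(object@targets))
    msg <- c(msg, "targets must be named by year")
  if (length(msg)) msg else TRUE
})

#' PriorityRanking: hierarchical conservation rank surface
#'
#' The output of the iterative cell-removal prioritization: a rank in (0, 1]
#' per cell (1 = most important, removed last), the removal order, and the
#' per-feature representation curves tracked during removal.
#'
#' @slot grid the ranked [GridGeometry-class].
#' @slot rank numeric matrix of ranks in (0, 1].
#' @slot removalOrder integer vector of 0-based cell ids in removal order
#'   (first removed = least valuable).
#' @slot representation data.frame: \code{fraction_removed} plus one column of
#'   remaining-fraction per feature, recorded after each removal round.
#' @slot rule removal rule used, "ABF" or "CAZ".
#' @slot warp integer, cells removed per round.
#'
#' @exportClass PriorityRanking
setClass("PriorityRanking",
  representation(grid = "GridGeometry", rank = "matrix",
                 removalOrder = "integer", representation = "data.frame",
                 rule = "character", warp = "integer"))

setValidity("PriorityRanking", function(object) {
  msg <- character()
  g <- object@grid
  n <- g@nrow * g@ncol
  if (!identical(dim(object@rank), c(g@nrow, g@ncol)))
    msg <- c(msg, "rank matrix must match the grid")
  if (any(object@rank <= 0 | object@rank > 1))
    msg <- c(msg, "ranks must lie in (0, 1]")
  if (length(object@removalOrder) != n ||
      !setequal(object@removalOrder, seq_len(n) - 1L))
    msg <- c(msg, "removalOrder must be a permutation of all cell ids")
  if (!object@rule %in% c("ABF", "CAZ"))
    msg <- c(msg, "rule must be ABF or CAZ")
  if (length(msg)) msg else TRUE
})

#' ScenarioEnsemble: Monte-Carlo samples of an annual quantity
#'
#' Draws of a scenario output (period-mean forest NBE, national anthropogenic
#' total, ...) with the seed and draw count recorded; summaries are the sample
#' mean and the empirical 95% percentile interval.
#'
#' @slot label scenario x climate x period label.
#' @slot samples numeric draws (TgCO2eq a-1).
#' @slot n integer, draws attempted.
#' @slot nFailed integer, draws that failed and were excluded.
#' @slot seed integer root seed.
#'
#' @exportClass ScenarioEnsemble
setClass("ScenarioEnsemble",
  representation(label = "character", samples = "numeric", n = "integer",
                 nFailed = "integer", seed = "integer"),
  prototype(nFailed = 0L))

setValidity("ScenarioEnsemble", function(object) {
  if (length(object@samples) + object@nFailed != object@n)
    return("samples + failed draws must equal n")
  TRUE
})

#' BudgetTable: land-use GHG budget
#'
#' Per-land-use emissions, sinks, net emissions (TgCO2eq a-1) and carbon
#' storage (TgC), with a total row. Net and total values are always computed,
#' never taken from input; validity asserts internal consistency.
#'
#' @slot data data.frame with columns \code{land_use}, \code{area_km2},
#'   \code{area_pct}, \code{emissions}, \code{sinks}, \code{net},
#'   \code{c_storage}; last row is the total.
#'
#' @exportClass BudgetTable
setClass("BudgetTable", representation(data = "data.frame"))

setValidity("BudgetTable", function(object) {
  d <- object@data
  need <- c("land_use", "area_km2", "area_pct", "emissions", "sinks", "net",
            "c_storage")
  if (!all(need %in% names(d)))
    return(paste("budget table lacks columns:",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  msg <- character()
  if (tail(d$land_use, 1) != "total") return("last row must be the total")
  body <- d[-nrow(d), ]
  tot <- d[nrow(d), ]
  if (max(abs(body$net - (body$emissions + body$sinks))) > 1e-9)
    msg <- c(msg, "net must equal emissions + sinks")
  for (col in c("area_km2", "emissions", "sinks", "net", "c_storage"))
    if (abs(tot[[col]] - sum(body[[col]])) > 1e-6)
      msg <- c(msg, sprintf("total row inconsistent in column '%s'", col))
  if (abs(sum(body$area_pct) - 100) > 0.5)
    msg <- c(msg, "area percentages must sum to 100 up to rounding")
  if (length(msg)) msg else TRUE
})

#' ServiceAccount: climate-regulation ecosystem service account
#'
#' Ecosystem-accounting (SEEA-style) climate regulation services for a scope:
#' net carbon sequestration (equal to NBE, source-positive) and carbon storage
#' (above-ground plus soil, with the soil share truncated by a configurable
#' fraction standing in for the 0.3 m accounting depth), plus the economic
#' value of the storage at a CO2 price.
#'
#' @slot scope "currently_protected", "target_10pct" or "whole_region".
#' @slot netSequestration TgCO2eq a-1 (negative = sink).
#' @slot cStorage TgC.
#' @slot soilTruncationFraction fraction of modelled soil C counted.
#' @slot economicValue M EUR.
#' @slot price EUR per tCO2 used in the valuation.
#'
#' @exportClass ServiceAccount
setClass("ServiceAccount",
  representation(scope = "character", netSequestration = "numeric",
                 cStorage = "numeric", soilTruncationFraction = "numeric",
                 economicValue = "numeric", price = "numeric"))

setValidity("ServiceAccount", function(object) {
  msg <- character()
  if (object@cStorage < 0) msg <- c(msg, "storage must be >= 0")
  if (object@soilTruncationFraction < 0 || object@soilTruncationFraction > 1)
    msg <- c(msg, "soilTruncationFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
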