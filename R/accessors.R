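# Accessor and show methods. Slot access stays internal to the package;
# user code goes through these.

#' @rdname Landscape-class
#' @export
setMethod("regionTable", "Landscape", function(object) object@regions)

#' @rdname Landscape-class
#' @export
setMethod("segmentTable", "Landscape", function(object) object@segments)

#' @rdname Landscape-class
#' @export
setMethod("protectedMask", "Landscape", function(object) object@protectedMask)

#' @rdname GridGeometry-class
#' @export
setMethod("gridGeometry", "Landscape", function(object) object@grid)

#' @rdname GridGeometry-class
#' @export
setMethod("gridGeometry", "FeatureStack", function(object) object@grid)

#' @rdname GridGeometry-class
#' @export
setMethod("gridGeometry", "EmissionInventory", function(object) object@grid)

#' @rdname GridGeometry-class
#' @export
setMethod("gridGeometry", "PriorityRanking", function(object) object@grid)

#' @rdname Landscape-class
#' @export
setMethod("regionTable", "EmissionInventory", function(object) {
  data.frame(region_id = sort(unique(as.vector(object@regionMap))))
})

#' Region id map of a landscape
#'
#' @param object a [Landscape-class] or [EmissionInventory-class].
#' @return integer matrix of region ids, one per grid cell.
#' @export
regionMap <- function(object) object@regionMap

#' @rdname FeatureStack-class
#' @export
setMethod("featureValues", "FeatureStack", function(object) object@features)

#' @rdname FeatureStack-class
#' @export
setMethod("featureNames", "FeatureStack",
          function(object) dimnames(object@features)[[3]])

#' @rdname FeatureStack-class
#' @export
setMethod("featureWeights", "FeatureStack", function(object) object@weights)

#' @rdname EmissionInventory-class
#' @export
setMethod("pointSources", "EmissionInventory",
          function(object) object@pointSources)

#' @rdname EmissionInventory-class
#' @export
setMethod("areaSources", "EmissionInventory",
          function(object) object@areaSources)

#' @rdname EmissionInventory-class
#' @export
setMethod("nationalTotal", "EmissionInventory", function(object, gas = NULL) {
  ps <- object@pointSources
  gasOf <- function(nm) sub("^.*\\|", "", nm)
  keepA <- names(object@areaSources)
  if (!is.null(gas)) {
    stopifnot(gas %in% .gasLevels)
    ps <- ps[ps$gas == gas, , drop = FALSE]
    keepA <- keepA[gasOf(keepA) == gas]
  }
  sum(ps$emission) +
    sum(vapply(object@areaSources[keepA], sum, numeric(1)))
})

#' @rdname PriorityRanking-class
#' @export
setMethod("rankSurface", "PriorityRanking", function(object) object@rank)

#' @rdname PriorityRanking-class
#' @export
setMethod("removalOrder", "PriorityRanking", function(object)
  object@removalOrder)

#' @rdname PriorityRanking-class
#' @export
setMethod("representationCurves", "PriorityRanking",
          function(object) object@representation)

#' @rdname ScenarioEnsemble-class
#' @export
setMethod("ensembleSamples", "ScenarioEnsemble",
          function(object) object@samples)

#' @rdname ScenarioEnsemble-class
#' @export
setMethod("ensembleSummary", "ScenarioEnsemble",
          function(object, level = 0.95) {
  a <- (1 - level) / 2
  q <- unname(stats::quantile(object@samples, c(a, 1 - a), type = 7))
  data.frame(label = object@label, mean = mean(object@samples),
             lower = q[1], upper = q[2], n = length(object@samples),
             n_failed = object@nFailed)
})

#' @rdname BudgetTable-class
#' @export
setMethod("budgetData", "BudgetTable", function(object) object@data)

#' @rdname ClimateSeries-class
#' @export
setMethod("climateData", "ClimateSeries", function(object) object@data)

## show methods -------------------------------------------------------------

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d cells of %g m (origin %g, %g)\n",
              object@nrow, object@ncol, object@cellsize,
              object@origin[1], object@origin[2]))
})

setMethod("show", "Landscape", function(object) {
  g <- object@grid
  cat(sprintf("Landscape: %d regions, %d forest segments on a %d x %d grid (%g m cells)\n",
              nrow(object@regions), nrow(object@segments),
              g@nrow, g@ncol, g@cellsize))
  cat(sprintf("  forest area %.1f km2 of %.1f km2 land (%.0f%%); %.1f%% of cells protected\n",
              sum(object@regions$forest_area_km2),
              sum(object@regions$land_area_km2),
              100 * sum(object@regions$forest_area_km2) /
                sum(object@regions$land_area_km2),
              100 * mean(object@protectedMask)))
})

setMethod("show", "ClimateSeries", function(object) {
  d <- object@data
  cat(sprintf("ClimateSeries ('%s'): %d years %d-%d, mean T %.1f degC, CO2 %.0f-%.0f ppm\n",
              object@scenario, nrow(d), min(d$year), max(d$year),
              mean(d$temperature), min(d$co2), max(d$co2)))
})

setMethod("show", "FeatureStack", function(object) {
  cat(sprintf("FeatureStack: %d layers on %d x %d grid\n",
              dim(object@features)[3], object@grid@nrow, object@grid@ncol))
  cat("  layers:", paste(featureNames(object), collapse = ", "), "\n")
})

setMethod("show", "EmissionInventory", function(object) {
  cat(sprintf("EmissionInventory (%s, year %d): %d point sources, %d area layers\n",
              object@scenario, object@year, nrow(object@pointSources),
              length(object@areaSources)))
  cat(sprintf("  national total %.2f TgCO2eq a-1%s\n", nationalTotal(object),
              if (object@spatialValid) "" else " (national level only)"))
})

setMethod("show", "PriorityRanking", function(object) {
  cat(sprintf("PriorityRanking (%s, warp %d): %d cells ranked\n",
              object@rule, object@warp, length(object@removalOrder)))
})

setMethod("show", "ScenarioEnsemble", function(object) {
  s <- ensembleSummary(object)
  cat(sprintf("ScenarioEnsemble '%s': n = %d, mean %.2f, 95%% (%.2f, %.2f)\n",
              object@label, s$n, s$mean, s$lower, s$upper))
})

setMethod("show", "BudgetTable", function(object) {
  cat("Land-use GHG budget (TgCO2eq a-1; storage TgC):\n")
  d <- object@data
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], round, 1)
  print(d, row.names = FALSE)
})

setMethod("show", "ServiceAccount", function(object) {
  cat(sprintf("ServiceAccount [%s]: net sequestration %.2f TgCO2eq a-1, storage %.1f TgC, value %.0f MEUR (at %g EUR/tCO2)\n",
              object@scope, object@netSequestration, object@cStorage,
              object@economicValue, object@price))
})

setMethod("show", "HarvestScenario", function(object) {
  cat(sprintf("HarvestScenario %s (x%.1f): %d target years, mean target %.3g m3 a-1\n",
              object@name, object@intensityMultiplier, length(object@targets),
              if (length(object@targets)) mean(object@targets) else 0))
})

setMethod("show", "ScenarioTrajectory", function(object) {
  cat(sprintf("ScenarioTrajectory %s%s: ", object@name,
              if (object@ccsFlag) " (with CCS assumption)" else ""))
  cat(paste(sprintf("%d: %.1f", object@anchorYears, object@totals),
            collapse = "; "), "\n")
})
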