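#' @rdname Landscape-class
#' @param object,x an object.
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))

#' @rdname Landscape-class
#' @export
setGeneric("segmentTable", function(object) standardGeneric("segmentTable"))

#' @rdname GridGeometry-class
#' @param object an object carrying a grid.
#' @export
setGeneric("gridGeometry", function(object) standardGeneric("gridGeometry"))

#' @rdname Landscape-class
#' @export
setGeneric("protectedMask", function(object) standardGeneric("protectedMask"))

#' @rdname FeatureStack-class
#' @param object a \code{FeatureStack} or \code{PriorityRanking}.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname FeatureStack-class
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname FeatureStack-class
#' @export
setGeneric("featureWeights", function(object) standardGeneric("featureWeights"))

#' @rdname EmissionInventory-class
#' @param object an \code{EmissionInventory}.
#' @param gas optional gas to restrict to.
#' @export
setGeneric("nationalTotal",
           function(object, gas = NULL) standardGeneric("nationalTotal"))

#' @rdname EmissionInventory-class
#' @export
setGeneric("pointSources", function(object) standardGeneric("pointSources"))

#' @rdname EmissionInventory-class
#' @export
setGeneric("areaSources", function(object) standardGeneric("areaSources"))

#' @rdname PriorityRanking-class
#' @param object a \code{PriorityRanking}.
#' @export
setGeneric("rankSurface", function(object) standardGeneric("rankSurface"))

#' @rdname PriorityRanking-class
#' @export
setGeneric("removalOrder", function(object) standardGeneric("removalOrder"))

#' @rdname PriorityRanking-class
#' @export
setGeneric("representationCurves",
           function(object) standardGeneric("representationCurves"))

#' @rdname ScenarioEnsemble-class
#' @param object a \code{ScenarioEnsemble}.
#' @export
setGeneric("ensembleSamples",
           function(object) standardGeneric("ensembleSamples"))

#' @rdname ScenarioEnsemble-class
#' @param level interval coverage, default 0.95.
#' @export
setGeneric("ensembleSummary",
           function(object, level = 0.95) standardGeneric("ensembleSummary"))

#' @rdname BudgetTable-class
#' @param object a \code{BudgetTable} or \code{ClimateSeries}.
#' @export
setGeneric("budgetData", function(object) standardGeneric("budgetData"))

#' @rdname ClimateSeries-class
#' @param object a \code{ClimateSeries}.
#' @export
setGeneric("climateData", function(object) standardGeneric("climateData"))
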