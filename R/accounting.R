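# Integration: land-use budget tables, regional nets, Monte-Carlo ensembles,
# neutrality probability, climate-regulation services and valuation.

#' Convert a gas mass flux to CO2 equivalents
#'
#' Linear conversion with 100-year global warming potentials; CO2's factor
#' is exactly 1.
#'
#' @param massFlux mass flux in Tg of the gas per year (vectorized).
#' @param gas "CO2", "CH4" or "N2O" (recycled against \code{massFlux}).
#' @param gwpSet named numeric of warming potentials.
#' @return TgCO2eq a-1.
#' @export
#' @examples
#' co2eq(1, "CH4")
co2eq <- function(massFlux, gas,
                  gwpSet = c(CO2 = 1, CH4 = 25, N2O = 298)) {
  if (!all(gas %in% names(gwpSet)))
    stop("unknown gas: ", paste(setdiff(gas, names(gwpSet)), collapse = ", "),
         call. = FALSE)
  massFlux * unname(gwpSet[gas])
}

#' Reference land-use flux and storage constants
#'
#' Per-land-use GHG emissions, sinks (TgCO2eq a-1), areas (km2) and carbon
#' storages (TgC) for the mainland-Finland reference budget the package's
#' budget table reproduces. Non-forest classes are accounting constants (the
#' package does not model them); forest values are the reference multi-year
#' averages and are replaced by simulation output in pipeline runs.
#'
#' @return data.frame with one row per land-use class.
#' @export
landUseReference <- function() {
  data.frame(
    land_use = c("forests", "arable", "surface_waters", "wetland",
                 "artificial"),
    area_km2 = c(211130, 22537, 33896, 31534, 7973),
    emissions = c(61.6, 12.2, 13.4, 14.3, 45.7),
    sinks = c(-89.3, 0, 0, -3.9, 0),
    c_storage = c(924 + 2617, 487, 615, 2365, 0))
}

#' Build a land-use GHG budget table
#'
#' Computes net emissions (emissions + sinks) per land-use class and the
#' total row from the component fluxes; nets and totals are always computed
#' here, never taken from input. Validity of the result asserts internal
#' consistency (net = emissions + sinks, totals = column sums, area shares
#' sum to 100).
#'
#' @param classes data.frame with columns \code{land_use}, \code{area_km2},
#'   \code{emissions}, \code{sinks} and optionally \code{c_storage}; one row
#'   per land-use class, no total row.
#' @return a [BudgetTable-class].
#' @export
#' @examples
#' bt <- buildBudgetTable(landUseReference())
#' budgetData(bt)
buildBudgetTable <- function(classes = landUseReference()) {
  need <- c("land_use", "area_km2", "emissions", "sinks")
  if (!all(need %in% names(classes)))
    stop("missing land-use class columns: ",
         paste(setdiff(need, names(classes)), collapse = ", "),
         call. = FALSE)
  if (anyNA(classes[need]))
    stop("missing values in land-use classes", call. = FALSE)
  d <- classes
  if (!"c_storage" %in% names(d)) d$c_storage <- 0
  totalArea <- sum(d$area_km2)
  d$area_pct <- if (totalArea > 0) 100 * d$area_km2 / totalArea else 0
  d$net <- d$emissions + d$sinks
  tot <- data.frame(land_use = "total", area_km2 = sum(d$area_km2),
                    emissions = sum(d$emissions), sinks = sum(d$sinks),
                    c_storage = sum(d$c_storage),
                    area_pct = if (totalArea > 0) 100 else 0,
                    net = sum(d$net))
  cols <- c("land_use", "area_km2", "area_pct", "emissions", "sinks", "net",
            "c_storage")
  new("BudgetTable", data = rbind(d[cols], tot[cols]))
}

#' Regional net GHG emissions
#'
#' Elementwise sum of forest NBE and anthropogenic totals per region; the
#' sum of regional nets equals the national net exactly.
#'
#' @param forestNbeByRegion data.frame \code{region_id}, \code{nbe}
#'   (TgCO2eq a-1).
#' @param anthroByRegion data.frame \code{region_id}, \code{emission}
#'   (TgCO2eq a-1).
#' @return data.frame \code{region_id}, \code{forest_nbe}, \code{anthro},
#'   \code{net}.
#' @export
regionalNetEmissions <- function(forestNbeByRegion, anthroByRegion) {
  if (!setequal(forestNbeByRegion$region_id, anthroByRegion$region_id))
    stop("region sets differ between forest and anthropogenic inputs",
         call. = FALSE)
  f <- forestNbeByRegion[order(forestNbeByRegion$region_id), ]
  a <- anthroByRegion[order(anthroByRegion$region_id), ]
  data.frame(region_id = f$region_id, forest_nbe = f$nbe,
             anthro = a$emission, net = f$nbe + a$emission)
}

# sample one named parameter set from distribution specs
.sampleParams <- function(dists) {
  lapply(dists, function(d) {
    switch(d$dist,
      point = d$value,
      normal = stats::rnorm(1, d$mean, d$sd),
      uniform = stats::runif(1, d$min, d$max),
      lognormal = stats::rlnorm(1, d$meanlog, d$sdlog),
      triangular = {
        tri <- .solveTriangular(d$mean, d$lower, d$upper)
        .rtriangular(1, tri["a"], tri["c"], tri["b"])
      },
      stop(sprintf("unknown distribution '%s'", d$dist), call. = FALSE))
  })
}

#' Direct Monte-Carlo ensemble of a simulator output
#'
#' Runs \code{n} independent end-to-end draws: each draw samples every named
#' parameter from its distribution, derives a per-draw sub-seed from the
#' root seed, calls the simulator and records its numeric result. Failed
#' draws are excluded and counted. The summary is the sample mean and the
#' empirical 95% percentile interval.
#'
#' @param simulator function(params, seed) returning a single numeric.
#' @param parameterDistributions named list of distribution specs, each a
#'   list with \code{dist} ("point", "normal", "uniform", "lognormal",
#'   "triangular") and its parameters.
#' @param n number of draws (>= 2).
#' @param seed integer root seed.
#' @param label ensemble label.
#' @return a [ScenarioEnsemble-class].
#' @export
#' @examples
#' ens <- runEnsemble(function(p, seed) p$x,
#'                    list(x = list(dist = "normal", mean = 0, sd = 1)),
#'                    n = 100, seed = 1)
#' ensembleSummary(ens)
runEnsemble <- function(simulator, parameterDistributions, n, seed = 1L,
                        label = "ensemble") {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  draws <- numeric(0)
  nFailed <- 0L
  for (i in seq_len(n)) {
    subSeed <- seedStream(seed, "ensemble", i)
    set.seed(subSeed)
    params <- .sampleParams(parameterDistributions)
    val <- tryCatch(simulator(params, subSeed), error = function(e) NA_real_)
    if (is.na(val)) nFailed <- nFailed + 1L else draws <- c(draws, val)
  }
  new("ScenarioEnsemble", label = label, samples = draws, n = as.integer(n),
      nFailed = nFailed, seed = as.integer(seed))
}

#' Probability of carbon neutrality
#'
#' Fraction of cross-paired draws for which forest NBE plus anthropogenic
#' emissions is at or below zero (sources balanced by the forest sink).
#' Draws are paired independently: every forest draw against every
#' anthropogenic draw.
#'
#' @param forestSamples draws of forest NBE, TgCO2eq a-1 (negative = sink).
#' @param anthroSamples draws of the national anthropogenic total.
#' @return probability in \[0, 1\].
#' @export
#' @examples
#' neutralityProbability(c(-50, -40), c(20, 30))
neutralityProbability <- function(forestSamples, anthroSamples) {
  if (!length(forestSamples) || !length(anthroSamples))
    stop("empty sample sets", call. = FALSE)
  a <- sort(anthroSamples)
  # count, per forest draw, the anthro draws with f + a <= 0
  counts <- findInterval(-forestSamples, a)
  sum(counts) / (as.numeric(length(forestSamples)) * length(a))
}

#' Climate-regulation service account
#'
#' Ecosystem-accounting services of a forested scope: net carbon
#' sequestration (period-mean NBE over the scope) and carbon storage
#' (biomass plus soil carbon at period end, the soil share scaled by a
#' truncation fraction standing in for the 0.3 m accounting depth), with the
#' storage valued at a CO2 price.
#'
#' @param run a [runScenario()] result.
#' @param landscape the simulated [Landscape-class].
#' @param scopeMask logical matrix on the landscape grid (cells in scope);
#'   NULL for the whole landscape.
#' @param period \code{c(first, last)} years for the sequestration mean and
#'   end-of-period storage; defaults to the whole run.
#' @param scope label for the account.
#' @param soilTruncationFraction fraction of modelled soil C counted
#'   (default 1; the pool model has no depth profile).
#' @param price EUR per tCO2 for the storage valuation.
#' @return a [ServiceAccount-class].
#' @export
climateServices <- function(run, landscape, scopeMask = NULL, period = NULL,
                            scope = "whole_region",
                            soilTruncationFraction = 1, price = 70) {
  grid <- gridGeometry(landscape)
  seg <- segmentTable(landscape)
  inScope <- if (is.null(scopeMask)) rep(TRUE, nrow(seg)) else {
    if (!identical(dim(scopeMask), c(grid@nrow, grid@ncol)))
      stop("scope mask does not match the landscape grid", call. = FALSE)
    scopeMask[.cellMatIndex(seg$cell_id, grid)]
  }
  years <- run$years
  if (is.null(period)) period <- range(years)
  sel <- years >= period[1] & years <= period[2]
  if (!any(sel)) stop("period outside the run years", call. = FALSE)

  if (!any(inScope)) {
    return(new("ServiceAccount", scope = scope, netSequestration = 0,
               cStorage = 0,
               soilTruncationFraction = soilTruncationFraction,
               economicValue = 0, price = price))
  }
  nbe <- mean(colSums(run$segNbeTg[inScope, sel, drop = FALSE]))
  endIdx <- max(which(sel))
  areaHa <- seg$area_m2 / 1e4
  soilEnd <- run$segSoil[, endIdx]
  biomassEnd <- run$segStorage[, endIdx] - soilEnd
  storage <- sum((biomassEnd[inScope] +
                    soilTruncationFraction * soilEnd[inScope]) *
                   areaHa[inScope]) / 1e6
  new("ServiceAccount", scope = scope, netSequestration = nbe,
      cStorage = storage,
      soilTruncationFraction = soilTruncationFraction,
      economicValue = economicValue(storage, price), price = price)
}

#' Economic value of a carbon storage
#'
#' \code{value = storage (TgC) x 44/12 x price (EUR/tCO2)}, reported in
#' millions of euros: 1 TgC is 1e6 tC, so the value in MEUR equals
#' \code{storage x 44/12 x price}.
#'
#' @param storageTgC carbon storage, TgC (>= 0).
#' @param price EUR per tCO2 (>= 0).
#' @return value in MEUR.
#' @export
#' @examples
#' economicValue(4500, 70)   # ~1.155e6 MEUR
economicValue <- function(storageTgC, price = 70) {
  if (any(storageTgC < 0)) stop("storage must be >= 0", call. = FALSE)
  if (any(price < 0)) stop("price must be >= 0", call. = FALSE)
  cToCO2eq(storageTgC) * price
}
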