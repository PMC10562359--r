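# Synthetic anthropogenic emission inventory: point sources per region plus
# six proxy-allocated area-source sectors on a coarse grid.

#' Default emission-inventory generation parameters
#'
#' National total, base year, the point/area sector split and sector x gas
#' shares of the national total. Defaults give a 2019-style inventory of
#' 54.1 TgCO2eq a-1 with 55% in point sources (energy, industry) and the
#' remainder across the six area-source sectors (traffic exhaust, machinery
#' and off-road, small-scale wood combustion, other small-scale combustion,
#' agriculture, waste management).
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
emissionConfig <- function(...) {
  cfg <- list(
    nationalTotal = 54.1,   # TgCO2eq a-1
    baseYear = 2019L,
    areaCellSize = 250,     # m
    # when TRUE, nationalTotal is read as the total of referenceAreaKm2 and
    # scaled to the landscape's land area, keeping the per-area emission
    # intensity realistic for small demonstration landscapes
    scalePerArea = FALSE,
    referenceAreaKm2 = 307070,
    pointSourcesPerRegion = 2L,
    # sector x gas shares of the national total; point rows are facility
    # sources, area rows are proxy-allocated
    sectorShares = data.frame(
      sector = c("energy", "industry",
                 "traffic_exhaust", "machinery_offroad",
                 "wood_combustion", "wood_combustion",
                 "other_small_combustion",
                 "agriculture", "agriculture", "agriculture",
                 "waste_management", "waste_management"),
      gas = c("CO2", "CO2", "CO2", "CO2", "CH4", "N2O", "CO2",
              "CO2", "CH4", "N2O", "CH4", "N2O"),
      type = c("point", "point", rep("area", 10)),
      share = c(0.35, 0.20, 0.20, 0.05, 0.010, 0.005, 0.04,
                0.010, 0.040, 0.065, 0.025, 0.005)))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown emission config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$nationalTotal < 0)
    stop("nationalTotal must be >= 0", call. = FALSE)
  if (abs(sum(cfg$sectorShares$share) - 1) > 1e-8)
    stop("sector shares must sum to 1", call. = FALSE)
  cfg
}

.areaSectors <- c("traffic_exhaust", "machinery_offroad", "wood_combustion",
                  "other_small_combustion", "agriculture",
                  "waste_management")

# Coarse-grid geometry covering the landscape extent, and the region map at
# that resolution (cell-centre rule against the landscape's Voronoi regions).
.coarseGrid <- function(landscape, cellSize) {
  g <- gridGeometry(landscape)
  extX <- g@ncol * g@cellsize
  extY <- g@nrow * g@cellsize
  cg <- gridGeom(max(1, ceiling(extY / cellSize)),
                 max(1, ceiling(extX / cellSize)), cellSize, g@origin)
  ctr <- .cellCentres(cg)
  col <- pmin(g@ncol, pmax(1, ceiling((ctr[, "x"] - g@origin[1]) /
                                        g@cellsize)))
  row <- pmin(g@nrow, pmax(1, ceiling((g@origin[2] - ctr[, "y"]) /
                                        g@cellsize)))
  rm <- regionMap(landscape)
  cellRegion <- rm[cbind(row, col)]
  regionMat <- matrix(NA_integer_, cg@nrow, cg@ncol)
  regionMat[.cellMatIndex(seq_len(nCells(cg)) - 1L, cg)] <- cellRegion
  list(grid = cg, regionMap = regionMat)
}

#' Generate a synthetic anthropogenic emission inventory
#'
#' Builds population, road and open-land proxy surfaces on the coarse
#' area-source grid, allocates the configured area-sector totals over them,
#' and places point sources (energy, industry) at population maxima within
#' each region. The inventory's national total equals the configured total
#' exactly.
#'
#' @param landscape a [Landscape-class] (provides extent and regions).
#' @param config list from [emissionConfig()].
#' @param seed integer root seed.
#' @return an [EmissionInventory-class].
#' @export
generateEmissionInventory <- function(landscape, config = emissionConfig(),
                                      seed = 1L) {
  set.seed(seedStream(seed, "emissions"))
  if (isTRUE(config$scalePerArea))
    config$nationalTotal <- config$nationalTotal *
      sum(regionTable(landscape)$land_area_km2) / config$referenceAreaKm2
  cg <- .coarseGrid(landscape, config$areaCellSize)
  grid <- cg$grid
  n <- nCells(grid)

  # proxies: clustered population, smoothed road density, open (non-forest)
  # land for agriculture
  popNoise <- matrix(stats::rexp(n)^2, grid@nrow, grid@ncol)
  population <- .smoothMatrix(popNoise, 2)
  roads <- .smoothMatrix(matrix(stats::runif(n), grid@nrow, grid@ncol), 3) +
    0.5 * population
  segCounts <- tabulate(segmentTable(landscape)$cell_id + 1L,
                        nCells(gridGeometry(landscape)))
  # open land: coarse cells with few forest segments under them
  lsGrid <- gridGeometry(landscape)
  forestShare <- .smoothMatrix(
    .vecToMatrix(pmin(1, segCounts / 2), lsGrid), 2)
  ctr <- .cellCentres(grid)
  col <- pmin(lsGrid@ncol, pmax(1, ceiling((ctr[, "x"] - lsGrid@origin[1]) /
                                             lsGrid@cellsize)))
  row <- pmin(lsGrid@nrow, pmax(1, ceiling((lsGrid@origin[2] - ctr[, "y"]) /
                                             lsGrid@cellsize)))
  open <- matrix(pmax(0, 1 - forestShare[cbind(row, col)]),
                 grid@nrow, grid@ncol)
  if (sum(open) == 0) open[] <- 1

  proxies <- list(traffic_exhaust = roads,
                  machinery_offroad = 0.5 * roads + 0.5 * open,
                  wood_combustion = population,
                  other_small_combustion = population,
                  agriculture = open,
                  waste_management = population)

  sh <- config$sectorShares
  areaTotals <- sh[sh$type == "area", c("sector", "gas")]
  areaTotals$total <- config$nationalTotal *
    sh$share[sh$type == "area"]
  areaGrid <- allocateAreaSources(areaTotals, proxies)

  # point sources at per-region population maxima
  pointRows <- sh[sh$type == "point", , drop = FALSE]
  regions <- regionTable(landscape)$region_id
  popVec <- .matrixToVec(population, grid)
  regVec <- .matrixToVec(cg$regionMap + 0, grid)
  ps <- list()
  sid <- 0L
  for (i in seq_len(nrow(pointRows))) {
    secTotal <- config$nationalTotal * pointRows$share[i]
    # split the sector total over regions proportionally to population mass
    regMass <- vapply(regions, function(r) sum(popVec[regVec == r]),
                      numeric(1))
    regShare <- regMass / sum(regMass)
    for (j in seq_along(regions)) {
      k <- config$pointSourcesPerRegion
      w <- stats::rgamma(k, shape = 1.5)
      for (m in seq_len(k)) {
        sid <- sid + 1L
        ps[[sid]] <- data.frame(
          source_id = sid, region_id = regions[j],
          sector = pointRows$sector[i], gas = pointRows$gas[i],
          emission = secTotal * regShare[j] * w[m] / sum(w))
      }
    }
  }
  ps <- do.call(rbind, ps)

  new("EmissionInventory", grid = grid, pointSources = ps,
      areaSources = areaGrid, sectors = .areaSectors,
      regionMap = cg$regionMap, baseYear = as.integer(config$baseYear),
      scenario = "base", year = as.integer(config$baseYear),
      spatialValid = TRUE)
}
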