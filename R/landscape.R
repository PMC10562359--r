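# Synthetic study-area generator: regions, forest segments, protection mask.

#' Default landscape generation parameters
#'
#' Returns the full parameter list understood by [generateLandscape()], with
#' defaults emulating a boreal forest-dominated study area: 18 regions, 69%
#' forest cover, mean forest-segment size 3926 m2, a pine-dominated species
#' mix, a quarter of forest on drained peat, and one region whose existing
#' protection already exceeds 10% (as in the northernmost region of the
#' system the generator emulates). Any subset can be overridden via
#' \code{...}; unknown names are an error.
#'
#' @param ... named overrides of the defaults.
#' @return named list of generation parameters.
#' @export
#' @examples
#' cfg <- landscapeConfig(nRegions = 4, gridNrow = 20, gridNcol = 20)
landscapeConfig <- function(...) {
  cfg <- list(
    nRegions = 18L,
    gridNrow = 48L, gridNcol = 48L, cellSize = 96,
    forestFraction = 0.69,
    # per-region existing protected fraction of forest area; a scalar is
    # recycled; the default elevates region 1 above the 10% target
    protectedFraction = NULL,
    protectedFractionDefault = 0.06,
    protectedFractionRegion1 = 0.12,
    poorlyProductiveFraction = 0.10,
    meanSegmentArea = 3926,
    speciesMix = c(pine = 0.5, spruce = 0.3, broadleaf = 0.2),
    soilMix = c(mineral = 0.75, drained_peat = 0.25),
    mineralFertilityMix = c(herb_rich = 0.1, mesic = 0.5, sub_xeric = 0.4),
    peatFertilityMix = c(nutrient_rich_peat = 0.5, nutrient_poor_peat = 0.5),
    ageMean = 60, ageSd = 35,
    maxStandVolume = 300,       # m3/ha asymptote of the age-volume curve
    volumeNoiseSd = 0.15        # lognormal sd of volume around the curve
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown landscape config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  .validateLandscapeConfig(cfg)
  cfg
}

.checkMix <- function(mix, what) {
  if (any(mix < 0 | mix > 1) || abs(sum(mix) - 1) > 1e-8)
    stop(sprintf("%s proportions must lie in [0,1] and sum to 1", what),
         call. = FALSE)
}

.validateLandscapeConfig <- function(cfg) {
  if (cfg$nRegions < 1) stop("nRegions must be >= 1", call. = FALSE)
  if (cfg$forestFraction < 0 || cfg$forestFraction > 1)
    stop("forestFraction must lie in [0, 1]", call. = FALSE)
  pf <- cfg$protectedFraction
  if (!is.null(pf) && any(pf < 0 | pf > 1))
    stop("protectedFraction must lie in [0, 1]", call. = FALSE)
  .checkMix(cfg$speciesMix, "species")
  .checkMix(cfg$soilMix, "soil")
  .checkMix(cfg$mineralFertilityMix, "mineral fertility")
  .checkMix(cfg$peatFertilityMix, "peat fertility")
  if (cfg$poorlyProductiveFraction < 0 || cfg$poorlyProductiveFraction > 1)
    stop("poorlyProductiveFraction must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

# Resolve the per-region protected fractions from the config.
.protectedFractions <- function(cfg) {
  if (!is.null(cfg$protectedFraction))
    return(rep_len(cfg$protectedFraction, cfg$nRegions))
  pf <- rep(cfg$protectedFractionDefault, cfg$nRegions)
  pf[1] <- cfg$protectedFractionRegion1
  pf
}

#' Generate a synthetic study area
#'
#' Builds a full [Landscape-class]: a Voronoi partition of the master grid
#' into regions, forest cells drawn to match the configured forest fraction,
#' forest segments splitting each forest cell (mean segment size
#' \code{meanSegmentArea}), per-segment attributes drawn from the configured
#' mixtures, an existing-reserve mask reaching each region's configured
#' protected fraction, and management classes (protected / productive /
#' poorly productive). Deterministic for a fixed seed; segment areas sum
#' exactly to each region's forest area.
#'
#' @param config list from [landscapeConfig()].
#' @param seed integer root seed.
#' @return a [Landscape-class].
#' @export
#' @examples
#' ls <- generateLandscape(landscapeConfig(nRegions = 3, gridNrow = 16,
#'                                         gridNcol = 16), seed = 1)
#' regionTable(ls)
generateLandscape <- function(config = landscapeConfig(), seed = 1L) {
  .validateLandscapeConfig(config)
  set.seed(seedStream(seed, "landscape"))
  grid <- gridGeom(config$gridNrow, config$gridNcol, config$cellSize)
  n <- nCells(grid)
  cellAreaM2 <- grid@cellsize^2

  # Voronoi partition of cells into regions; each region anchored at its
  # seed cell so no region can come out empty.
  ctr <- .cellCentres(grid)
  seedCells <- sample.int(n, config$nRegions)
  d2 <- outer(ctr[, "x"], ctr[seedCells, "x"], "-")^2 +
        outer(ctr[, "y"], ctr[seedCells, "y"], "-")^2
  regionOfCell <- max.col(-d2, ties.method = "first")
  regionOfCell[seedCells] <- seq_len(config$nRegions)

  regionMap <- matrix(NA_integer_, grid@nrow, grid@ncol)
  regionMap[.cellMatIndex(seq_len(n) - 1L, grid)] <- regionOfCell

  pf <- .protectedFractions(config)
  regions <- data.frame(
    region_id = seq_len(config$nRegions),
    name = sprintf("region_%02d", seq_len(config$nRegions)),
    land_area_km2 = as.numeric(tabulate(regionOfCell, config$nRegions)) *
      cellAreaM2 / 1e6,
    forest_area_km2 = 0, protected_fraction = 0)

  # Forest cells per region, hitting the configured forest share by count.
  forestCell <- logical(n)
  for (r in seq_len(config$nRegions)) {
    cells <- which(regionOfCell == r)
    k <- round(config$forestFraction * length(cells))
    if (k > 0) forestCell[sample(cells, k)] <- TRUE
    regions$forest_area_km2[r] <- k * cellAreaM2 / 1e6
  }

  # Existing reserves: per region, grow a cluster of forest cells around a
  # random reserve centre until the configured protected share is reached.
  protectedCellFlag <- logical(n)
  for (r in seq_len(config$nRegions)) {
    cells <- which(regionOfCell == r & forestCell)
    if (!length(cells) || pf[r] <= 0) next
    centre <- cells[sample.int(length(cells), 1)]
    ord <- cells[order((ctr[cells, "x"] - ctr[centre, "x"])^2 +
                       (ctr[cells, "y"] - ctr[centre, "y"])^2)]
    k <- ceiling(pf[r] * length(cells))
    protectedCellFlag[ord[seq_len(min(k, length(ord)))]] <- TRUE
    regions$protected_fraction[r] <- min(k, length(ord)) / length(cells)
  }
  protectedMask <- matrix(FALSE, grid@nrow, grid@ncol)
  protectedMask[.cellMatIndex(which(protectedCellFlag) - 1L, grid)] <- TRUE

  # Split each forest cell into segments whose areas sum exactly to the cell
  # area; expected segment count matches the configured mean segment size.
  fCells <- which(forestCell)
  nSegPerCell <- pmax(1L, stats::rpois(length(fCells),
                                       cellAreaM2 / config$meanSegmentArea))
  segCell <- rep(fCells, nSegPerCell)
  nSeg <- length(segCell)
  w <- stats::rgamma(nSeg, shape = 2, rate = 1)   # within-cell area shares
  areaM2 <- unlist(lapply(split(w, rep(seq_along(fCells), nSegPerCell)),
                          function(v) cellAreaM2 * v / sum(v)),
                   use.names = FALSE)

  species <- sample(names(config$speciesMix), nSeg, replace = TRUE,
                    prob = config$speciesMix)
  soil <- sample(names(config$soilMix), nSeg, replace = TRUE,
                 prob = config$soilMix)
  fert <- character(nSeg)
  isPeat <- soil == "drained_peat"
  if (any(!isPeat))
    fert[!isPeat] <- sample(names(config$mineralFertilityMix), sum(!isPeat),
                            replace = TRUE, prob = config$mineralFertilityMix)
  if (any(isPeat))
    fert[isPeat] <- sample(names(config$peatFertilityMix), sum(isPeat),
                           replace = TRUE, prob = config$peatFertilityMix)

  shp <- (config$ageMean / config$ageSd)^2
  age <- round(stats::rgamma(nSeg, shape = shp,
                             rate = shp / config$ageMean))
  protectedSeg <- protectedCellFlag[segCell]
  # reserves hold older stands on average; also gives prioritization signal
  age[protectedSeg] <- age[protectedSeg] + 40
  vol <- config$maxStandVolume * (1 - exp(-age / 40))^1.5 *
    exp(stats::rnorm(nSeg, 0, config$volumeNoiseSd))

  mgmt <- rep("productive", nSeg)
  mgmt[protectedSeg] <- "protected"
  idxProd <- which(mgmt == "productive")
  nPoor <- round(config$poorlyProductiveFraction * length(idxProd))
  if (nPoor > 0)
    mgmt[sample(idxProd, nPoor)] <- "poorly_productive"

  yearsSince <- ifelse(mgmt == "productive",
                       round(stats::rexp(nSeg, 1 / 20)), 80 +
                         round(stats::rexp(nSeg, 1 / 40)))
  intensity <- ifelse(mgmt == "productive",
                      stats::runif(nSeg, 0.3, 1), 0)

  segments <- data.frame(
    segment_id = seq_len(nSeg),
    region_id = regionOfCell[segCell],
    cell_id = segCell - 1L,
    area_m2 = areaM2,
    species = species, site_fertility = fert, soil = soil,
    age = as.numeric(age), stem_volume = vol,
    management_class = mgmt,
    years_since_action = as.numeric(yearsSince),
    mgmt_intensity = intensity,
    stringsAsFactors = FALSE)

  new("Landscape", grid = grid, regions = regions, segments = segments,
      regionMap = regionMap, protectedMask = protectedMask)
}
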