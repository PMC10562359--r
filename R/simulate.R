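# Per-segment annual simulation: GPP -> allocation -> harvest -> soil -> NBE.

#' Net biome exchange from its components
#'
#' \code{NBE = NEE + harvested biomass + CH4 + N2O from organic soils}, all
#' in TgCO2eq a-1, source-positive. An exact sum; negative NBE means the
#' forest is a net GHG sink.
#'
#' @param nee net ecosystem exchange, TgCO2eq a-1 (positive = source).
#' @param harvestedBiomass harvested biomass, TgCO2eq a-1.
#' @param ch4,n2o organic-soil fluxes, TgCO2eq a-1.
#' @return NBE, TgCO2eq a-1.
#' @export
#' @examples
#' computeNBE(-89.3, 59.7, 0.4, 1.4)
computeNBE <- function(nee, harvestedBiomass, ch4 = 0, n2o = 0) {
  nee + harvestedBiomass + ch4 + n2o
}

# fapar from stand volume; a small floor stands in for post-clearcut
# regeneration so stands regrow.
.faparOfVolume <- function(vol, params) {
  pmax(0.05, params$faparMax * (1 - exp(-vol / params$faparVolScale)))
}

#' Run a forest carbon scenario
#'
#' Simulates every forest segment through the years covered: light-use
#' efficiency GPP, annual allocation to growth and litter, harvest
#' allocation to the oldest productive stands, the soil pool cascade on
#' mineral soils and empirical net coefficients on drained peat, and NBE
#' aggregation to the landscape and regions. Deterministic given the inputs
#' (all stochasticity lives in the generated landscape and climate).
#'
#' @param landscape a [Landscape-class].
#' @param harvest a [HarvestScenario-class] (see [harvestScenario()]).
#' @param climate a [ClimateSeries-class] covering \code{years}.
#' @param years simulation years; default the climate's years.
#' @param newProtectionMask optional logical matrix on the landscape grid;
#'   segments in masked cells are treated as protected (no harvest).
#' @param params list from [forestParams()].
#' @return a list with elements
#' \describe{
#'   \item{fluxes}{data.frame per year: gpp/npp/rh/nee (gC m-2 a-1,
#'     area-weighted), harvested_volume_m3, harvested_biomass_co2, ch4 and
#'     n2o (TgCO2eq a-1), nee_tg, nbe (TgCO2eq a-1), biomass_tgc, soil_tgc,
#'     total_storage_tgc (TgC), harvest_infeasible.}
#'   \item{regionFluxes}{data.frame per year x region: nee_tg,
#'     harvested_biomass_co2, ch4, n2o, nbe (TgCO2eq a-1).}
#'   \item{initialStates,finalStates}{per-segment state tables
#'     (biomass_c tC/ha, stem_volume m3/ha, age, soil_c tC/ha).}
#'   \item{segNbeTg}{matrix segment x year of NBE contributions, TgCO2eq.}
#'   \item{segStorage}{matrix segment x year of end-of-year carbon storage,
#'     tC/ha (biomass + soil).}
#'   \item{segCumNeeC,segCumExportC}{per-segment cumulative NEE carbon and
#'     exported harvest carbon, tC/ha, for closure checks.}
#'   \item{scenario,climateScenario,years,params}{run metadata.}
#' }
#' @export
runScenario <- function(landscape, harvest, climate, years = NULL,
                        newProtectionMask = NULL,
                        params = forestParams()) {
  seg <- segmentTable(landscape)
  grid <- gridGeometry(landscape)
  cd <- climateData(climate)
  if (is.null(years)) years <- cd$year
  if (!all(years %in% cd$year))
    stop("simulation years outside climate coverage", call. = FALSE)
  if (!is.null(newProtectionMask)) {
    if (!identical(dim(newProtectionMask), c(grid@nrow, grid@ncol)))
      stop(sprintf("protection mask geometry (%s) does not match grid (%d x %d)",
                   paste(dim(newProtectionMask), collapse = " x "),
                   grid@nrow, grid@ncol), call. = FALSE)
  }

  n <- nrow(seg)
  areaHa <- seg$area_m2 / 1e4
  isPeat <- seg$soil == "drained_peat"
  eligible <- rep(TRUE, n)
  if (!is.null(newProtectionMask))
    eligible <- !newProtectionMask[.cellMatIndex(seg$cell_id, grid)]

  # state
  vol <- seg$stem_volume
  biomass <- vol * params$cDensity
  age <- seg$age
  litter0 <- params$turnover * biomass
  pools <- .soilSteadyState(litter0, params)
  peatC <- rep(0, n)
  peatC[isPeat] <- params$peatInitC
  pools[isPeat, ] <- 0
  soilC <- rowSums(pools) + peatC

  # constant peat gas fluxes (coefficient x area)
  ch4SegTg <- rep(0, n); n2oSegTg <- rep(0, n); peatNetC <- rep(0, n)
  if (any(isPeat)) {
    pf <- peatSoilFlux(seg$site_fertility[isPeat], seg$area_m2[isPeat],
                       params)
    ch4SegTg[isPeat] <- pf$ch4
    n2oSegTg[isPeat] <- pf$n2o
    peatNetC[isPeat] <- params$peatCoefCO2[seg$site_fertility[isPeat]] / 100
  }

  initialStates <- data.frame(segment_id = seg$segment_id,
                              biomass_c = biomass, stem_volume = vol,
                              age = age, soil_c = soilC)
  ny <- length(years)
  segNbeTg <- matrix(0, n, ny, dimnames = list(NULL, years))
  segStorage <- matrix(0, n, ny, dimnames = list(NULL, years))
  segSoil <- matrix(0, n, ny, dimnames = list(NULL, years))
  cumNeeC <- numeric(n); cumExportC <- numeric(n)
  fluxes <- vector("list", ny)
  regionFluxes <- vector("list", ny)
  wArea <- seg$area_m2 / sum(seg$area_m2)
  regionF <- factor(seg$region_id, levels = regionTable(landscape)$region_id)

  states <- seg  # working copy for harvest allocation
  states$eligible <- eligible

  for (t in seq_len(ny)) {
    yr <- years[t]
    cl <- cd[cd$year == yr, ]

    fapar <- .faparOfVolume(vol, params)
    gpp <- gppLUE(cl$radiation, cl$temperature, cl$vpd, cl$co2,
                  params$swiDefault, fapar, params)
    al <- allocateAnnual(gpp, biomass, params)
    nppC <- al$npp / 100                      # tC/ha
    litter <- al$litter

    # growth before harvest; harvest sees the post-growth stand
    biomass <- biomass + nppC - litter
    vol <- biomass / params$cDensity
    states$stem_volume <- vol
    states$age <- age

    hv <- applyHarvest(states, harvest, yr, params)
    biomass <- pmax(biomass - hv$removedBiomass, 0)  # clear FP dust at 0
    vol <- biomass / params$cDensity
    exportC <- hv$removedBiomass - hv$residueLitter    # tC/ha exported

    age <- age + 1
    age[hv$clearcut] <- 0

    # soil: cascade on mineral, net empirical coefficient on drained peat
    litterIn <- litter + hv$residueLitter
    rh <- numeric(n)
    if (any(!isPeat)) {
      st <- soilStep(pools[!isPeat, , drop = FALSE], litterIn[!isPeat],
                     cl$temperature, params)
      pools[!isPeat, ] <- st$pools
      rh[!isPeat] <- st$rh
    }
    if (any(isPeat)) {
      rh[isPeat] <- litterIn[isPeat] + peatNetC[isPeat]
      peatC[isPeat] <- peatC[isPeat] - peatNetC[isPeat]
    }
    soilC <- rowSums(pools) + peatC

    neeC <- rh - nppC                          # tC/ha, source-positive
    cumNeeC <- cumNeeC + neeC
    cumExportC <- cumExportC + exportC

    neeSegTg <- cToCO2eq(neeC * areaHa) / 1e6  # TgCO2eq per segment
    harvSegTg <- cToCO2eq(exportC * areaHa) / 1e6
    segNbeTg[, t] <- computeNBE(neeSegTg, harvSegTg, ch4SegTg, n2oSegTg)
    segStorage[, t] <- biomass + soilC
    segSoil[, t] <- soilC

    fluxes[[t]] <- data.frame(
      year = yr,
      gpp = sum(gpp * wArea), npp = sum(al$npp * wArea),
      rh = sum(rh * 100 * wArea), nee = sum(neeC * 100 * wArea),
      litter = sum(litterIn * 100 * wArea),
      harvested_volume_m3 = hv$totalRemovedM3,
      harvested_biomass_co2 = sum(harvSegTg),
      ch4 = sum(ch4SegTg), n2o = sum(n2oSegTg),
      nee_tg = sum(neeSegTg),
      nbe = computeNBE(sum(neeSegTg), sum(harvSegTg), sum(ch4SegTg),
                       sum(n2oSegTg)),
      biomass_tgc = sum(biomass * areaHa) / 1e6,
      soil_tgc = sum(soilC * areaHa) / 1e6,
      total_storage_tgc = sum((biomass + soilC) * areaHa) / 1e6,
      harvest_infeasible = hv$infeasible)

    regionFluxes[[t]] <- data.frame(
      year = yr,
      region_id = regionTable(landscape)$region_id,
      nee_tg = as.numeric(rowsum(neeSegTg, regionF)),
      harvested_biomass_co2 = as.numeric(rowsum(harvSegTg, regionF)),
      ch4 = as.numeric(rowsum(ch4SegTg, regionF)),
      n2o = as.numeric(rowsum(n2oSegTg, regionF)))
  }
  regionFluxes <- do.call(rbind, regionFluxes)
  regionFluxes$nbe <- computeNBE(regionFluxes$nee_tg,
                                 regionFluxes$harvested_biomass_co2,
                                 regionFluxes$ch4, regionFluxes$n2o)

  list(
    scenario = harvest@name, climateScenario = climate@scenario,
    years = years,
    fluxes = do.call(rbind, fluxes),
    regionFluxes = regionFluxes,
    initialStates = initialStates,
    finalStates = data.frame(segment_id = seg$segment_id,
                             biomass_c = biomass, stem_volume = vol,
                             age = age, soil_c = soilC),
    segNbeTg = segNbeTg, segStorage = segStorage, segSoil = segSoil,
    segCumNeeC = cumNeeC, segCumExportC = cumExportC,
    params = params)
}

#' Period averages of annual fluxes
#'
#' Averages scenario outputs over reporting windows (defaults matching the
#' package's standard reporting periods 2017-2025, 2026-2033, 2034-2050).
#'
#' @param fluxes the \code{fluxes} data.frame of a [runScenario()] result.
#' @param windows list of \code{c(first, last)} year pairs.
#' @return data.frame with one row per window: period label and period means
#'   of harvested volume (Mm3 if the input is m3), harvested biomass, NEE and
#'   NBE (TgCO2eq a-1), and end-of-period storage (TgC).
#' @export
periodAverages <- function(fluxes,
                           windows = list(c(2017, 2025), c(2026, 2033),
                                          c(2034, 2050))) {
  out <- lapply(windows, function(w) {
    d <- fluxes[fluxes$year >= w[1] & fluxes$year <= w[2], ]
    if (!nrow(d)) return(NULL)
    data.frame(period = sprintf("%d-%d", w[1], w[2]),
               harvested_volume_m3 = mean(d$harvested_volume_m3),
               harvested_biomass_co2 = mean(d$harvested_biomass_co2),
               nee_tg = mean(d$nee_tg), ch4 = mean(d$ch4), n2o = mean(d$n2o),
               nbe = mean(d$nbe),
               storage_tgc = d$total_storage_tgc[nrow(d)])
  })
  do.call(rbind, out)
}

#' Maximum carbon-storage potential under no harvesting
#'
#' Runs the no-harvest scenario over a long horizon (default 100 years) and
#' returns the end-of-horizon total ecosystem carbon storage (biomass +
#' soil), the theoretical storage the landscape approaches when harvesting
#' stops.
#'
#' @param landscape a [Landscape-class].
#' @param climate a [ClimateSeries-class] covering the horizon.
#' @param horizonYears years to run (0 returns current storage).
#' @param params list from [forestParams()].
#' @return list with \code{storage_tgc} (TgC at the horizon) and
#'   \code{trajectory} (data.frame year, total_storage_tgc).
#' @export
maxStoragePotential <- function(landscape, climate, horizonYears = 100,
                                params = forestParams()) {
  if (horizonYears < 0) stop("horizon must be >= 0", call. = FALSE)
  seg <- segmentTable(landscape)
  if (horizonYears == 0) {
    biomass <- seg$stem_volume * params$cDensity
    pools <- .soilSteadyState(params$turnover * biomass, params)
    soilC <- rowSums(pools)
    isPeat <- seg$soil == "drained_peat"
    soilC[isPeat] <- params$peatInitC
    cur <- sum((biomass + soilC) * seg$area_m2 / 1e4) / 1e6
    return(list(storage_tgc = cur,
                trajectory = data.frame(year = integer(),
                                        total_storage_tgc = numeric())))
  }
  yrs <- climateData(climate)$year
  years <- yrs[seq_len(min(horizonYears, length(yrs)))]
  if (length(years) < horizonYears)
    stop("climate series shorter than the requested horizon", call. = FALSE)
  sc <- harvestScenario("NoHarv", years, baseTarget = 0)
  run <- runScenario(landscape, sc, climate, years, params = params)
  list(storage_tgc = run$fluxes$total_storage_tgc[length(years)],
       trajectory = run$fluxes[, c("year", "total_storage_tgc")],
       run = run)
}
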