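# Harvest scenarios and yearly harvest allocation.

#' Construct a harvest-intensity scenario
#'
#' Builds the yearly removal targets (m3 of exported stemwood per year).
#' Years up to \code{historicalEnd} use realised removals for every scenario;
#' later years use \code{baseTarget} scaled by the scenario's intensity
#' multiplier (BaseHarv 1.0, LowHarv 0.6, MaxHarv 1.2, NoHarv 0).
#'
#' @param name "BaseHarv", "LowHarv", "MaxHarv" or "NoHarv".
#' @param years integer vector of simulation years.
#' @param baseTarget BaseHarv-level yearly removal target, m3 a-1.
#' @param realizedRemovals optional named numeric (by year) of realised
#'   removals for the historical window; defaults to \code{baseTarget}.
#' @param historicalEnd last year of the historical window (default 2021).
#' @return a [HarvestScenario-class].
#' @export
#' @examples
#' harvestScenario("LowHarv", 2015:2030, baseTarget = 1e5)
harvestScenario <- function(name = c("BaseHarv", "LowHarv", "MaxHarv",
                                     "NoHarv"),
                            years, baseTarget,
                            realizedRemovals = NULL,
                            historicalEnd = 2021) {
  name <- match.arg(name)
  mult <- unname(.harvestMultipliers[name])
  stopifnot(length(baseTarget) == 1L, baseTarget >= 0)
  targets <- numeric(length(years))
  names(targets) <- years
  hist <- years <= historicalEnd
  histTarget <- if (is.null(realizedRemovals)) {
    rep(baseTarget, sum(hist))
  } else {
    out <- realizedRemovals[as.character(years[hist])]
    out[is.na(out)] <- baseTarget
    out
  }
  targets[hist] <- histTarget
  targets[!hist] <- baseTarget * mult
  new("HarvestScenario", name = name, intensityMultiplier = mult,
      targets = targets)
}

#' Allocate a year's harvest target over segments
#'
#' Removals go to productive segments only; protected and poorly productive
#' segments are never cut. Oldest (then highest-volume) stands are taken
#' first; stands at or above the clearcut age are clearcut, younger ones
#' thinned by a fixed volume fraction. The boundary stand is cut partially
#' so the total exported volume equals the year's target exactly when
#' feasible; an infeasible target removes everything eligible and is
#' reported, not raised. A configured fraction of the removed biomass stays
#' on site as harvest-residue litter; stand age resets on (full) clearcut.
#'
#' @param states data.frame of current segment states with columns
#'   \code{area_m2}, \code{stem_volume} (m3/ha), \code{age},
#'   \code{management_class} and \code{eligible} (logical; FALSE forces
#'   NoHarv, e.g. inside a proposed protection mask).
#' @param scenario a [HarvestScenario-class].
#' @param year the simulation year (must have a target).
#' @param params list from [forestParams()].
#' @return list with per-segment vectors \code{removedVolumeM3} (exported),
#'   \code{removedBiomass} and \code{residueLitter} (tC/ha),
#'   \code{clearcut} (logical full clearcut), plus \code{totalRemovedM3},
#'   \code{target} and \code{infeasible}.
#' @export
applyHarvest <- function(states, scenario, year, params = forestParams()) {
  yr <- as.character(year)
  if (!yr %in% names(scenario@targets))
    stop(sprintf("no harvest target defined for year %s", yr), call. = FALSE)
  target <- unname(scenario@targets[yr])
  n <- nrow(states)
  removedVol <- numeric(n)          # exported m3 per segment
  clearcut <- logical(n)
  eligible <- states$management_class == "productive" &
    (if ("eligible" %in% names(states)) states$eligible else TRUE)

  out <- list(removedVolumeM3 = removedVol,
              removedBiomass = numeric(n), residueLitter = numeric(n),
              clearcut = clearcut, totalRemovedM3 = 0, target = target,
              infeasible = FALSE)
  if (target <= 0 || !any(eligible)) {
    out$infeasible <- target > 0 && !any(eligible)
    return(out)
  }

  areaHa <- states$area_m2 / 1e4
  rFrac <- params$residueFraction
  idx <- which(eligible & states$stem_volume > 0)
  if (!length(idx)) {
    out$infeasible <- TRUE
    return(out)
  }
  # removable stand volume (m3): full on clearcut-age stands, thinning share
  # below; exported share excludes residues
  cut <- states$age[idx] >= params$clearcutAge
  standRemovable <- states$stem_volume[idx] * areaHa[idx] *
    ifelse(cut, 1, params$thinFraction)
  exportable <- (1 - rFrac) * standRemovable
  ord <- order(-states$age[idx], -states$stem_volume[idx], idx)
  idx <- idx[ord]; cut <- cut[ord]; exportable <- exportable[ord]
  standRemovable <- standRemovable[ord]

  cumExp <- cumsum(exportable)
  last <- findInterval(target, c(0, cumExp), rightmost.closed = FALSE)
  # last = index of first segment at which cumulative export reaches target
  take <- rep(0, length(idx))
  if (last > length(idx) || cumExp[length(idx)] <= target) {
    take[] <- 1
    out$infeasible <- cumExp[length(idx)] < target
  } else {
    if (last > 1) take[seq_len(last - 1)] <- 1
    already <- if (last > 1) cumExp[last - 1] else 0
    take[last] <- (target - already) / exportable[last]
  }

  standRemoved <- standRemovable * take                      # m3 from stand
  removedVol[idx] <- (1 - rFrac) * standRemoved              # exported m3
  dV <- standRemoved / areaHa[idx]                           # m3/ha
  out$removedBiomass <- numeric(n)
  out$removedBiomass[idx] <- dV * params$cDensity            # tC/ha
  out$residueLitter <- numeric(n)
  out$residueLitter[idx] <- rFrac * dV * params$cDensity
  clearcut[idx] <- cut & take >= 1 - 1e-12
  out$removedVolumeM3 <- removedVol
  out$clearcut <- clearcut
  out$totalRemovedM3 <- sum(removedVol)
  out
}

#' Convert harvested stem volume to CO2-equivalent carbon
#'
#' \code{CO2eq = volume x cDensity x 44/12}: with the default carbon density
#' of 0.2 tC per m3, 81.5 Mm3 corresponds to 59.8 TgCO2eq.
#'
#' @param volumeMm3 harvested volume, Mm3 (>= 0).
#' @param cDensity carbon density of harvested volume, tC/m3.
#' @return TgCO2eq.
#' @export
#' @examples
#' harvestVolumeToCarbon(81.5)
harvestVolumeToCarbon <- function(volumeMm3, cDensity = 0.2) {
  if (any(volumeMm3 < 0)) stop("volume must be >= 0", call. = FALSE)
  cToCO2eq(volumeMm3 * cDensity)
}

#' Inverse of [harvestVolumeToCarbon()]
#' @param tgco2eq harvested biomass, TgCO2eq.
#' @inheritParams harvestVolumeToCarbon
#' @return volume, Mm3.
#' @export
carbonToHarvestVolume <- function(tgco2eq, cDensity = 0.2) {
  co2eqToC(tgco2eq) / cDensity
}
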