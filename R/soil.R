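# Soil carbon: a three-pool decay cascade for mineral soils and empirical
# net-balance coefficients for drained peatlands.

#' One annual step of the soil carbon pool cascade
#'
#' Each pool decays by \code{mass * min(1, k * g(T))} with
#' \eqn{g(T) = exp(s (T - T_{ref}))} increasing in temperature; a fixed
#' fraction of the decayed mass transfers to the next pool and the rest
#' leaves as heterotrophic respiration. Litter enters the fastest pool.
#' The decay fraction is capped at 1, so pools can never go negative, and
#' the step satisfies exact mass balance:
#' \code{sum(pools') - sum(pools) == litterInput - rh}.
#'
#' @param pools numeric matrix (units tC/ha; one row per segment, one column
#'   per pool) or a vector for a single segment.
#' @param litterInput litter entering the fastest pool this year, tC/ha.
#' @param temperature annual mean temperature, degC.
#' @param params list from [forestParams()].
#' @return list with \code{pools} (updated matrix) and \code{rh}
#'   (heterotrophic respiration, tC ha-1 a-1, one per segment).
#' @export
#' @examples
#' st <- soilStep(c(fast = 10, slow = 30, humus = 50), litterInput = 3,
#'                temperature = 3.5)
#' st$rh
soilStep <- function(pools, litterInput, temperature,
                     params = forestParams()) {
  if (any(litterInput < 0)) stop("litterInput must be >= 0", call. = FALSE)
  if (is.null(dim(pools))) pools <- matrix(pools, nrow = 1)
  k <- params$soilK; tr <- params$soilTransfer
  stopifnot(ncol(pools) == length(k), length(tr) == length(k),
            all(k >= 0), all(tr >= 0), all(tr < 1))
  g <- exp(params$soilTSens * (temperature - params$soilTRef))
  rh <- numeric(nrow(pools))
  transferIn <- numeric(nrow(pools))
  for (i in seq_along(k)) {
    decayed <- pools[, i] * pmin(1, k[i] * g)
    pools[, i] <- pools[, i] - decayed + transferIn
    rh <- rh + decayed * (1 - tr[i])
    transferIn <- decayed * tr[i]
  }
  # tr for the last pool is 0 by default; any configured residual transfer
  # would leave the system, so respire it instead to preserve mass balance
  rh <- rh + transferIn
  pools[, 1] <- pools[, 1] + litterInput
  if (any(pools < 0))
    stop("internal error: negative soil pool after step", call. = FALSE)
  list(pools = pools, rh = rh)
}

# Steady-state pool sizes for a constant litter input at g(T) = 1; used to
# initialise mineral-soil pools without a long spin-up transient.
.soilSteadyState <- function(litter, params = forestParams()) {
  k <- params$soilK; tr <- params$soilTransfer
  inflow <- litter
  pools <- matrix(0, length(litter), length(k))
  for (i in seq_along(k)) {
    pools[, i] <- inflow / min(1, max(k[i], .Machine$double.eps))
    inflow <- inflow * tr[i]
  }
  colnames(pools) <- names(k)
  pools
}

#' Drained-peatland soil GHG fluxes
#'
#' Empirical per-area soil coefficients for forestry-drained peat: the net
#' soil CO2 balance is positive (source) on nutrient-rich sites and a small
#' negative (sink) on nutrient-poor sites; CH4 and N2O are emitted only from
#' these organic soils. Fluxes are coefficient x area, converted to CO2
#' equivalents with the configured warming potentials.
#'
#' @param siteFertility "nutrient_rich_peat" or "nutrient_poor_peat"
#'   (vectorized). Calling this for a mineral-soil fertility class is an
#'   error.
#' @param areaM2 segment area, m2.
#' @param params list from [forestParams()].
#' @return list with \code{co2_soil}, \code{ch4}, \code{n2o}, each TgCO2eq
#'   a-1 (vectorized over segments).
#' @export
#' @examples
#' peatSoilFlux("nutrient_rich_peat", 1e6)$co2_soil > 0
peatSoilFlux <- function(siteFertility, areaM2, params = forestParams()) {
  if (!all(siteFertility %in% .peatFertility))
    stop("peatSoilFlux() applies only to drained peat fertility classes",
         call. = FALSE)
  if (any(areaM2 < 0)) stop("area must be >= 0", call. = FALSE)
  co2gC <- params$peatCoefCO2[siteFertility]           # gC m-2 a-1 net
  ch4g <- params$peatCH4KgHa * 0.1                     # kg/ha -> g/m2
  n2og <- params$peatN2OKgHa[siteFertility] * 0.1
  list(
    co2_soil = gCm2ToTg(cToCO2eq(unname(co2gC)), areaM2),
    ch4 = gCm2ToTg(unname(ch4g) * params$gwp[["CH4"]], areaM2),
    n2o = gCm2ToTg(unname(n2og) * params$gwp[["N2O"]], areaM2))
}
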