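# Light-use-efficiency GPP and annual allocation.

#' Forest simulator parameters
#'
#' All tunable parameters of the forest carbon simulator, with defaults for a
#' boreal conifer-dominated landscape. Units in comments; override any subset
#' via \code{...}.
#'
#' @param ... named overrides.
#' @return named list of parameters.
#' @export
forestParams <- function(...) {
  p <- list(
    eps = 1.1,             # light-use efficiency, gC per MJ absorbed PAR
    faparMax = 0.95,       # canopy absorption asymptote
    faparVolScale = 100,   # m3/ha scale of the volume->fapar curve
    tMin = -8, tOpt = 10,  # degC ramp of the temperature modifier
    vpdK = 0.25,           # kPa-1, exponential VPD limitation
    swOpt = 0.5,           # soil-water index at which water stops limiting
    swiDefault = 0.8,      # default annual soil-water index
    co2Beta = 0.6,         # log-CO2 fertilization slope
    co2Ref = 380,          # ppm reference for the CO2 modifier
    raFrac = 0.5,          # autotrophic respiration fraction of GPP
    turnover = 0.08,       # a-1, biomass litter turnover fraction
    cDensity = 0.2,        # tC per m3 stem volume (biomass <-> volume link)
    residueFraction = 0.3, # share of removed biomass left as litter
    clearcutAge = 80,      # a, stands at or above are clearcut, else thinned
    thinFraction = 0.3,    # volume share removed in a thinning
    soilK = c(fast = 0.5, slow = 0.05, humus = 0.005),   # a-1 decay rates
    soilTransfer = c(0.3, 0.2, 0),  # fraction of decay passed to next pool
    soilTRef = 3.5,        # degC reference for the decay modifier
    soilTSens = 0.07,      # degC-1, log-linear decay temperature sensitivity
    peatInitC = 100,       # tC/ha initial drained-peat soil store
    # net annual soil C balance of drained peat, gC m-2 a-1
    # (positive = net source on nutrient-rich sites, small net sink on poor)
    peatCoefCO2 = c(nutrient_rich_peat = 80, nutrient_poor_peat = -20),
    peatCH4KgHa = 2.5,     # kg CH4 ha-1 a-1 from organic soils
    peatN2OKgHa = c(nutrient_rich_peat = 1.5, nutrient_poor_peat = 0.3),
    gwp = c(CO2 = 1, CH4 = 25, N2O = 298)  # 100-year warming potentials
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown forest parameters: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  p
}

#' Annual GPP from a light-use-efficiency model
#'
#' \deqn{GPP = \epsilon \cdot fAPAR \cdot PAR \cdot f_T f_D f_W f_C}
#' with saturating-ramp modifiers for temperature, vapour pressure deficit and
#' soil water (each in \[0, 1\]) and a log-saturating CO2 fertilization factor
#' \eqn{f_C \ge 1}. All arguments are vectorized.
#'
#' @param radiation growing-season PAR, MJ m-2 a-1 (>= 0).
#' @param temperature annual mean temperature, degC.
#' @param vpd mean vapour pressure deficit, kPa.
#' @param co2 ambient CO2, ppm.
#' @param swi soil-water index in \[0, 1\].
#' @param fapar fraction of absorbed PAR in \[0, 1\].
#' @param params list from [forestParams()].
#' @return GPP, gC m-2 a-1.
#' @export
#' @examples
#' gppLUE(1800, 3.5, 0.5, 415, 0.8, 0.7)
gppLUE <- function(radiation, temperature, vpd, co2, swi = NULL, fapar = 1,
                   params = forestParams()) {
  if (any(radiation < 0)) stop("radiation must be >= 0", call. = FALSE)
  if (any(fapar < 0 | fapar > 1)) stop("fapar must lie in [0, 1]",
                                       call. = FALSE)
  if (is.null(swi)) swi <- params$swiDefault
  stopifnot(all(is.finite(radiation)), all(is.finite(temperature)),
            all(is.finite(vpd)), all(is.finite(co2)), all(is.finite(swi)))
  fT <- pmin(1, pmax(0, (temperature - params$tMin) /
                          (params$tOpt - params$tMin)))
  fD <- exp(-params$vpdK * pmax(vpd, 0))
  fW <- pmin(1, pmax(0, swi) / params$swOpt)
  fC <- pmax(1, 1 + params$co2Beta * log(co2 / params$co2Ref))
  params$eps * fapar * radiation * fT * fD * fW * fC
}

#' Fit the light-use efficiency to GPP observations
#'
#' Least-squares estimate of epsilon from observed GPP and known drivers:
#' the model is linear in epsilon, so the estimate is
#' \eqn{\hat\epsilon = \sum y x / \sum x^2} with x the modifier-weighted
#' absorbed radiation.
#'
#' @param gppObs observed GPP, gC m-2 a-1.
#' @param drivers data.frame with columns \code{radiation},
#'   \code{temperature}, \code{vpd}, \code{co2}, \code{swi}, \code{fapar}.
#' @param params list from [forestParams()] (its \code{eps} is ignored).
#' @return estimated epsilon, gC/MJ.
#' @export
fitLUE <- function(gppObs, drivers, params = forestParams()) {
  p1 <- params; p1$eps <- 1
  x <- gppLUE(drivers$radiation, drivers$temperature, drivers$vpd,
              drivers$co2, drivers$swi, drivers$fapar, p1)
  sum(gppObs * x) / sum(x * x)
}

#' Allocate annual GPP to respiration, growth and litter
#'
#' NPP is \code{(1 - raFrac) * GPP}; litter production is the turnover
#' fraction of standing biomass; the pre-harvest biomass change is NPP minus
#' litter. Carbon is closed: GPP = NPP + autotrophic respiration.
#'
#' @param gpp GPP, gC m-2 a-1 (vectorized).
#' @param biomassC standing biomass carbon, tC/ha.
#' @param params list from [forestParams()].
#' @return list with components \code{npp} (gC m-2 a-1), \code{ra}
#'   (autotrophic respiration, gC m-2 a-1), \code{litter} (tC ha-1 a-1) and
#'   \code{dBiomass} (pre-harvest biomass change, tC ha-1 a-1).
#' @export
allocateAnnual <- function(gpp, biomassC, params = forestParams()) {
  if (any(gpp < 0)) stop("gpp must be >= 0", call. = FALSE)
  npp <- (1 - params$raFrac) * gpp
  litter <- params$turnover * biomassC          # tC/ha
  list(npp = npp, ra = params$raFrac * gpp, litter = litter,
       dBiomass = npp / 100 - litter)           # gC m-2 == 0.01 tC/ha
}
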