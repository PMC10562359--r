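# Annual climate series generator: a trend-free "current" scenario and a
# stabilizing "warming" scenario (moderate-forcing style: linear trends in
# temperature and CO2 that plateau at a configured year).

#' Generate an annual climate series
#'
#' The \code{current} scenario is interannual noise around a fixed baseline
#' with constant CO2. The \code{warming} scenario adds linear trends in
#' temperature and CO2 that plateau after \code{plateauYear} (a
#' stabilization pathway of moderate radiative forcing). Radiation here is a
#' growing-season photosynthetically-active total; the simulator runs on
#' annual drivers.
#'
#' @param scenario "current" or "warming".
#' @param years integer vector of years (non-empty).
#' @param seed integer root seed.
#' @param baseline named list of baseline values: \code{temperature} (degC),
#'   \code{radiation} (MJ m-2 a-1 PAR), \code{precipitation} (mm),
#'   \code{vpd} (kPa), \code{co2} (ppm).
#' @param tempTrend warming trend, degC per year (warming scenario only).
#' @param co2Trend CO2 trend, ppm per year (warming scenario only).
#' @param plateauYear year after which the warming trends stop.
#' @param trendStartYear year the trends are anchored at.
#' @param interannualSd named list of interannual standard deviations for
#'   \code{temperature} (degC), and relative sds for \code{radiation},
#'   \code{precipitation} and \code{vpd}.
#' @return a [ClimateSeries-class].
#' @export
#' @examples
#' cl <- generateClimate("warming", 2015:2050, seed = 1)
#' head(climateData(cl))
generateClimate <- function(scenario = c("current", "warming"),
                            years = 2015:2050, seed = 1L,
                            baseline = list(temperature = 3.5,
                                            radiation = 1800,
                                            precipitation = 600,
                                            vpd = 0.5, co2 = 415),
                            tempTrend = 0.03, co2Trend = 2.0,
                            plateauYear = 2070, trendStartYear = 2015,
                            interannualSd = list(temperature = 0.6,
                                                 radiation = 0.04,
                                                 precipitation = 0.10,
                                                 vpd = 0.08)) {
  scenario <- match.arg(scenario)
  if (!length(years)) stop("years must be non-empty", call. = FALSE)
  set.seed(seedStream(seed, "climate"))
  n <- length(years)

  elapsed <- pmax(0, pmin(years, plateauYear) - trendStartYear)
  dT  <- if (scenario == "warming") tempTrend * elapsed else 0
  dC  <- if (scenario == "warming") co2Trend * elapsed else 0

  d <- data.frame(
    year = as.integer(years),
    temperature = baseline$temperature + dT +
      stats::rnorm(n, 0, interannualSd$temperature),
    radiation = baseline$radiation *
      exp(stats::rnorm(n, 0, interannualSd$radiation)),
    precipitation = baseline$precipitation *
      exp(stats::rnorm(n, 0, interannualSd$precipitation)),
    vpd = baseline$vpd * exp(stats::rnorm(n, 0, interannualSd$vpd)),
    co2 = baseline$co2 + dC)

  new("ClimateSeries", data = d, scenario = scenario)
}
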