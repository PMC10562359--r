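# Anthropogenic emission inventory: proxy allocation, scenario scaling,
# uncertainty sampling and regional aggregation.

#' Allocate national sector totals to an area-source grid
#'
#' Distributes each sector x gas national total over the grid proportionally
#' to a non-negative proxy surface (population density, road density, land
#' use, ...). Cells with zero proxy receive zero; column totals reproduce
#' the sector totals exactly up to floating-point.
#'
#' @param nationalSectorTotals data.frame with columns \code{sector},
#'   \code{gas}, \code{total} (TgCO2eq a-1, >= 0).
#' @param proxySurfaces named list of non-negative matrices (all the same
#'   shape), one per sector (keyed by sector name).
#' @return named list of emission matrices, keyed \code{"sector|gas"}.
#' @export
#' @examples
#' tot <- data.frame(sector = "traffic_exhaust", gas = "CO2", total = 10)
#' g <- allocateAreaSources(tot, list(traffic_exhaust = matrix(1, 2, 2)))
#' sum(g[["traffic_exhaust|CO2"]])
allocateAreaSources <- function(nationalSectorTotals, proxySurfaces) {
  stopifnot(all(c("sector", "gas", "total") %in%
                  names(nationalSectorTotals)))
  if (any(nationalSectorTotals$total < 0))
    stop("sector totals must be >= 0", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(nationalSectorTotals))) {
    sec <- nationalSectorTotals$sector[i]
    gas <- nationalSectorTotals$gas[i]
    tot <- nationalSectorTotals$total[i]
    proxy <- proxySurfaces[[sec]]
    if (is.null(proxy))
      stop(sprintf("no proxy surface for sector '%s'", sec), call. = FALSE)
    if (any(proxy < 0))
      stop(sprintf("proxy for sector '%s' has negative values", sec),
           call. = FALSE)
    s <- sum(proxy)
    if (s == 0 && tot > 0)
      stop(sprintf("all-zero proxy for sector '%s' with nonzero total", sec),
           call. = FALSE)
    out[[paste(sec, gas, sep = "|")]] <-
      if (tot == 0) proxy * 0 else proxy * (tot / s)
  }
  out
}

#' National emission scenario trajectories
#'
#' Constructors for the two standard national trajectories: \code{WEM}
#' ("with existing measures") and \code{WAM} ("with additional measures").
#' Anchor totals (TgCO2eq a-1) default to 54.1 (2019), 39.0 / 33.4 (2030)
#' and 22.9 / 8.6 (2050); the WAM 2050 total assumes large-scale carbon
#' capture, without which it is 17.6. Totals between anchors are
#' piecewise-linear.
#'
#' @param name "WEM" or "WAM".
#' @param anchorYears anchor years.
#' @param totals national totals at the anchors (capture-inclusive for WAM).
#' @param totalsNoCCS totals without the capture assumption.
#' @param ccsFlag whether the capture assumption applies (suppresses
#'   regional WAM output after 2030).
#' @return a [ScenarioTrajectory-class].
#' @export
#' @examples
#' wem <- scenarioTrajectory("WEM")
#' trajectoryTotal(wem, 2040)
scenarioTrajectory <- function(name = c("WEM", "WAM"),
                               anchorYears = c(2019, 2030, 2050),
                               totals = NULL, totalsNoCCS = NULL,
                               ccsFlag = NULL) {
  name <- match.arg(name)
  if (is.null(totals))
    totals <- if (name == "WEM") c(54.1, 39.0, 22.9) else c(54.1, 33.4, 8.6)
  if (is.null(totalsNoCCS))
    totalsNoCCS <- if (name == "WEM") totals else c(54.1, 33.4, 17.6)
  if (is.null(ccsFlag)) ccsFlag <- name == "WAM"
  new("ScenarioTrajectory", name = name, anchorYears = anchorYears,
      totals = totals, totalsNoCCS = totalsNoCCS, ccsFlag = ccsFlag)
}

#' @rdname scenarioTrajectory
#' @param trajectory a [ScenarioTrajectory-class].
#' @param year year within the trajectory span.
#' @param useCCS whether to read the capture-inclusive totals.
#' @export
trajectoryTotal <- function(trajectory, year, useCCS = trajectory@ccsFlag) {
  if (year < min(trajectory@anchorYears) || year > max(trajectory@anchorYears))
    stop(sprintf("year %d outside trajectory span %d-%d", year,
                 min(trajectory@anchorYears), max(trajectory@anchorYears)),
         call. = FALSE)
  tot <- if (useCCS) trajectory@totals else trajectory@totalsNoCCS
  stats::approx(trajectory@anchorYears, tot, xout = year)$y
}

#' Scale an inventory to a scenario year
#'
#' Applies the national relative change \code{total(year) / total(baseYear)}
#' to every point and area source (the same relative change for all
#' locations; point-source locations stay frozen at the base year). For the
#' WAM trajectory after 2030 under the carbon-capture assumption the result
#' is valid at national level only: the returned inventory carries
#' \code{spatialValid = FALSE} and any regional disaggregation refuses.
#'
#' @param inventory an [EmissionInventory-class].
#' @param trajectory a [ScenarioTrajectory-class].
#' @param year target year within the trajectory span.
#' @return a scaled [EmissionInventory-class].
#' @export
scaleToScenario <- function(inventory, trajectory, year) {
  base <- trajectoryTotal(trajectory, inventory@baseYear, useCCS = FALSE)
  nationalOnly <- trajectory@ccsFlag && trajectory@name == "WAM" &&
    year > 2030
  target <- trajectoryTotal(trajectory, year, useCCS = trajectory@ccsFlag)
  ratio <- target / base
  ps <- inventory@pointSources
  ps$emission <- ps$emission * ratio
  as2 <- lapply(inventory@areaSources, function(m) m * ratio)
  new("EmissionInventory", grid = inventory@grid, pointSources = ps,
      areaSources = as2, sectors = inventory@sectors,
      regionMap = inventory@regionMap, baseYear = inventory@baseYear,
      scenario = trajectory@name, year = as.integer(year),
      spatialValid = !nationalOnly)
}

# Solve an asymmetric triangular distribution (mode m) whose 2.5/97.5
# percentiles equal the stated interval endpoints.
.solveTriangular <- function(m, lo, hi, pTail = 0.025) {
  if (lo > m || hi < m)
    stop("uncertainty interval must bracket the mean", call. = FALSE)
  if (hi - lo <= 0) return(c(a = m, c = m, b = m))
  a <- lo - 0.5 * (m - lo); b <- hi + 0.5 * (hi - m)
  for (i in 1:200) {
    aNew <- if (m > lo) lo - sqrt(pTail * (b - a) * (m - a)) else m
    bNew <- if (hi > m) hi + sqrt(pTail * (b - a) * (b - m)) else m
    if (abs(aNew - a) < 1e-12 && abs(bNew - b) < 1e-12) break
    a <- aNew; b <- bNew
  }
  c(a = a, c = m, b = b)
}

.rtriangular <- function(n, a, c, b) {
  if (b - a <= 0) return(rep(c, n))
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc, a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Monte-Carlo samples of the national inventory total
#'
#' Draws the national CO2eq total from per-sector uncertainty distributions
#' (asymmetric triangular with mode at the sector mean, tails matched to the
#' stated 95% interval) and sums sectors per draw. Sectors are sampled
#' independently; empirical 2.5/97.5 percentiles of the sum converge to the
#' configured intervals when one sector dominates.
#'
#' @param intervals data.frame with columns \code{sector}, \code{mean},
#'   \code{lower}, \code{upper} (95% interval bracketing the mean).
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of \code{n} national totals.
#' @export
#' @examples
#' s <- sampleInventoryUncertainty(
#'   data.frame(sector = "all", mean = 54.1, lower = 48.1, upper = 59.4),
#'   n = 1000, seed = 1)
sampleInventoryUncertainty <- function(intervals, n, seed = 1L) {
  stopifnot(all(c("sector", "mean", "lower", "upper") %in% names(intervals)))
  if (any(intervals$lower > intervals$mean | intervals$upper < intervals$mean))
    stop("uncertainty intervals must bracket the sector means", call. = FALSE)
  set.seed(seedStream(seed, "inventory_uncertainty"))
  total <- numeric(n)
  for (i in seq_len(nrow(intervals))) {
    tri <- .solveTriangular(intervals$mean[i], intervals$lower[i],
                            intervals$upper[i])
    total <- total + .rtriangular(n, tri["a"], tri["c"], tri["b"])
  }
  total
}

#' Aggregate an inventory to regions
#'
#' Sums point sources by their region and area-source cells by the
#' cell-centre region assignment. Refuses when the inventory is valid at
#' national level only.
#'
#' @param inventory an [EmissionInventory-class].
#' @return data.frame with columns \code{region_id}, \code{sector},
#'   \code{gas}, \code{type} ("point"/"area"), \code{emission}; region
#'   totals sum to the national total exactly.
#' @export
aggregateInventoryToRegions <- function(inventory) {
  if (!inventory@spatialValid)
    stop(paste("regional output is suppressed for the WAM scenario after",
               "2030: the carbon-capture implementation it assumes has no",
               "regional allocation, so only the national total is valid"),
         call. = FALSE)
  rm <- inventory@regionMap
  if (anyNA(rm)) {
    bad <- which(is.na(rm))
    stop(sprintf("%d area cells outside all regions (first: %s)",
                 length(bad), paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  regionIds <- sort(unique(as.vector(rm)))
  rf <- factor(as.vector(rm), levels = regionIds)
  out <- list()
  for (nm in names(inventory@areaSources)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    sums <- rowsum(as.vector(inventory@areaSources[[nm]]), rf)
    out[[length(out) + 1L]] <- data.frame(
      region_id = regionIds, sector = parts[1], gas = parts[2],
      type = "area", emission = as.numeric(sums))
  }
  ps <- inventory@pointSources
  if (nrow(ps)) {
    agg <- stats::aggregate(emission ~ region_id + sector + gas, ps, sum)
    agg$type <- "point"
    out[[length(out) + 1L]] <- agg[, c("region_id", "sector", "gas", "type",
                                       "emission")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-region inventory totals
#'
#' @param inventory an [EmissionInventory-class].
#' @return data.frame \code{region_id}, \code{emission} (TgCO2eq a-1).
#' @export
regionalInventoryTotals <- function(inventory) {
  d <- aggregateInventoryToRegions(inventory)
  agg <- stats::aggregate(emission ~ region_id, d, sum)
  agg[order(agg$region_id), ]
}
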