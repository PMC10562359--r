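# Seed sub-streams, unit conversions and small grid helpers.

# Polynomial rolling hash of a string, positive and below 2^31. (Exact in
# double arithmetic: intermediate values stay below 2^53.)
.hashString <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Derive a named sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed through named
#' sub-streams ("landscape", "climate", "features", "ensemble", ...), so
#' stages are individually reproducible and adding draws to one stage never
#' perturbs another.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @param k optional integer index within the stream (e.g. draw number).
#' @return an integer seed in \[0, 2^31).
#' @export
#' @examples
#' seedStream(1, "landscape")
#' seedStream(1, "ensemble", 17)
seedStream <- function(seed, stream, k = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  as.integer((.hashString(paste(stream, k, sep = "#")) +
                as.numeric(seed) * 1000003) %% 2147483647)
}

## unit conversions ---------------------------------------------------------

#' Unit conversions used throughout the carbon accounting
#'
#' `cToCO2eq()` and `co2eqToC()` convert between carbon mass and CO2 mass
#' (factor 44/12, exact); they apply to any mass unit. `gCm2ToTg()` converts
#' an areal flux (gC m-2 a-1 or gCO2eq m-2 a-1) over an area in m2 to Tg a-1.
#'
#' @param x numeric value(s).
#' @param area_m2 area in square metres.
#' @return converted numeric.
#' @export
cToCO2eq <- function(x) x * (44 / 12)

#' @rdname cToCO2eq
#' @export
co2eqToC <- function(x) x * (12 / 44)

#' @rdname cToCO2eq
#' @export
gCm2ToTg <- function(x, area_m2) x * area_m2 / 1e12

## grid helpers -------------------------------------------------------------

#' Construct a grid geometry
#'
#' @param nrow,ncol grid dimensions.
#' @param cellsize cell edge length in metres.
#' @param origin numeric length 2, upper-left corner (x, y) in metres.
#' @return a [GridGeometry-class].
#' @export
#' @examples
#' gridGeom(10, 10, cellsize = 96)
gridGeom <- function(nrow, ncol, cellsize = 96, origin = c(0, 0)) {
  new("GridGeometry", nrow = as.integer(nrow), ncol = as.integer(ncol),
      cellsize = as.numeric(cellsize), origin = as.numeric(origin))
}

#' Number of cells in a grid
#' @param grid a [GridGeometry-class].
#' @export
nCells <- function(grid) as.numeric(grid@nrow) * grid@ncol

#' Compare two grid geometries
#' @param a,b [GridGeometry-class] objects.
#' @return TRUE if identical geometry.
#' @export
sameGrid <- function(a, b) {
  a@nrow == b@nrow && a@ncol == b@ncol &&
    isTRUE(all.equal(a@cellsize, b@cellsize)) &&
    isTRUE(all.equal(a@origin, b@origin))
}

.assertSameGrid <- function(a, b, what = "rasters") {
  if (!sameGrid(a, b))
    stop(sprintf("grid geometry mismatch between %s: %dx%d@%gm vs %dx%d@%gm",
                 what, a@nrow, a@ncol, a@cellsize, b@nrow, b@ncol, b@cellsize),
         call. = FALSE)
  invisible(TRUE)
}

# Cell ids are 0-based, row-major from the upper-left corner.
.cellRowCol <- function(cell_id, grid) {
  row <- cell_id %/% grid@ncol + 1L
  col <- cell_id %% grid@ncol + 1L
  cbind(row = row, col = col)
}

.rowColCell <- function(row, col, grid) {
  (row - 1L) * grid@ncol + (col - 1L)
}

# Matrix index (R column-major) for 0-based row-major cell ids.
.cellMatIndex <- function(cell_id, grid) {
  rc <- .cellRowCol(cell_id, grid)
  (rc[, "col"] - 1L) * grid@nrow + rc[, "row"]
}

# Cell-centre coordinates in metres.
.cellCentres <- function(grid) {
  ids <- seq_len(nCells(grid)) - 1L
  rc <- .cellRowCol(ids, grid)
  cbind(x = grid@origin[1] + (rc[, "col"] - 0.5) * grid@cellsize,
        y = grid@origin[2] - (rc[, "row"] - 0.5) * grid@cellsize)
}

# Simple separable mean-filter smoothing with reflecting edges; used by the
# synthetic generators for spatial autocorrelation.
.smoothMatrix <- function(m, range) {
  if (range <= 1) return(m)
  k <- as.integer(range)
  smooth1 <- function(v) {
    n <- length(v)
    idx <- seq_len(n)
    out <- stats::filter(c(rev(v[seq_len(k)]), v, rev(v[n + 1 - seq_len(k)])),
                         rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    as.numeric(out[k + idx])
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(m2, 1, smooth1))
}

# Deterministic config-hash for provenance metadata.
.configHash <- function(config) {
  .hashString(paste(deparse(config, control = "all"), collapse = ""))
}
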