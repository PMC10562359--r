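# Synthetic biodiversity feature layers: spatially autocorrelated, coupled to
# old/high-volume stands, with planted high-value hotspot clusters so that a
# prioritization run has recoverable signal.

# Shared internal: builds the per-cell stand-value index, hotspot centres and
# bump field. Both generateBdFeatures() and bdHotspots() derive from it, so
# the planted hotspots are recoverable for testing.
.bdScaffold <- function(landscape, autocorrRange, seed) {
  set.seed(seedStream(seed, "features"))
  grid <- gridGeometry(landscape)
  n <- nCells(grid)
  seg <- segmentTable(landscape)

  # area-weighted stand value (age x volume) per cell, scaled to [0, 1]
  sv <- seg$area_m2 * seg$age * pmax(seg$stem_volume, 1)
  cellValue <- numeric(n)
  agg <- rowsum(sv, seg$cell_id)
  cellValue[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  if (max(cellValue) > 0) cellValue <- cellValue / max(cellValue)

  sigma <- max(autocorrRange, 1) / 2   # bump radius in cells
  forestCells <- which(cellValue > 0)
  nHot <- max(3L, round(0.1 * length(forestCells) / (pi * sigma^2)))
  nHot <- min(nHot, length(forestCells))
  centres <- sample(forestCells, nHot, prob = cellValue[forestCells]^2)

  rc <- .cellRowCol(seq_len(n) - 1L, grid)
  crc <- .cellRowCol(centres - 1L, grid)
  bump <- numeric(n)
  for (i in seq_len(nHot)) {
    d2 <- (rc[, "row"] - crc[i, "row"])^2 + (rc[, "col"] - crc[i, "col"])^2
    bump <- bump + exp(-d2 / (2 * sigma^2))
  }
  list(grid = grid, n = n, cellValue = cellValue, bump = bump,
       centres = centres, sigma = sigma)
}

# cell-id vector -> matrix in grid layout
.vecToMatrix <- function(v, grid) {
  m <- matrix(0, grid@nrow, grid@ncol)
  m[.cellMatIndex(seq_along(v) - 1L, grid)] <- v
  m
}

.matrixToVec <- function(m, grid) m[.cellMatIndex(seq_len(nCells(grid)) - 1L, grid)]

#' Generate synthetic biodiversity feature layers
#'
#' Builds \code{nFeatures} non-negative raster layers on the landscape grid.
#' Each layer mixes (i) spatially autocorrelated noise (mean-filtered white
#' noise, filter half-width \code{autocorrRange} cells), (ii) a coupling to
#' old, high-volume stands, and (iii) shared high-value hotspot clusters
#' planted preferentially on valuable stands. With \code{autocorrRange = 1}
#' the layers degenerate to (near) white noise. All layers are weighted
#' equally by default.
#'
#' @param landscape a [Landscape-class].
#' @param nFeatures number of layers (>= 1).
#' @param autocorrRange autocorrelation range in cells; 1 = none.
#' @param seed integer root seed.
#' @return a [FeatureStack-class].
#' @seealso [bdHotspots()] for the planted hotspot mask.
#' @export
generateBdFeatures <- function(landscape, nFeatures = 6L, autocorrRange = 4,
                               seed = 1L) {
  if (nFeatures < 1) stop("nFeatures must be >= 1", call. = FALSE)
  sc <- .bdScaffold(landscape, autocorrRange, seed)
  grid <- sc$grid
  arr <- array(0, dim = c(grid@nrow, grid@ncol, nFeatures),
               dimnames = list(NULL, NULL,
                               sprintf("bd_feature_%02d", seq_len(nFeatures))))
  structured <- autocorrRange > 1
  for (j in seq_len(nFeatures)) {
    noise <- matrix(stats::runif(sc$n), grid@nrow, grid@ncol)
    if (structured) noise <- .smoothMatrix(noise, autocorrRange)
    noise <- noise - min(noise)
    if (max(noise) > 0) noise <- noise / max(noise)
    wStand <- if (structured) stats::runif(1, 0.3, 0.6) else 0
    wBump <- if (structured) 1.5 else 0
    layer <- 0.5 * noise + wStand * .vecToMatrix(sc$cellValue, grid) +
      wBump * .vecToMatrix(sc$bump, grid)
    arr[, , j] <- layer
  }
  w <- rep(1, nFeatures)
  names(w) <- dimnames(arr)[[3]]
  new("FeatureStack", grid = grid, features = arr, weights = w)
}

#' Planted biodiversity hotspot mask
#'
#' Recomputes (from the same seed) the hotspot clusters that
#' [generateBdFeatures()] planted, as a logical matrix marking cells within
#' one bump radius of a hotspot centre. Used to verify that prioritization
#' recovers planted signal.
#'
#' @inheritParams generateBdFeatures
#' @return logical matrix on the landscape grid.
#' @export
bdHotspots <- function(landscape, autocorrRange = 4, seed = 1L) {
  sc <- .bdScaffold(landscape, autocorrRange, seed)
  .vecToMatrix(sc$bump > exp(-0.5), sc$grid) > 0
}
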