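# Shared fixtures: small landscapes, feature-stack builders, and an
# independent brute-force greedy ranking oracle.

tinyLandscape <- function(seed = 1, nRegions = 3, nrow = 16, ncol = 16, ...) {
  generateLandscape(landscapeConfig(nRegions = nRegions, gridNrow = nrow,
                                    gridNcol = ncol, ...), seed = seed)
}

# FeatureStack from a list of matrices
makeStack <- function(layers, weights = NULL, cellsize = 96) {
  m1 <- layers[[1]]
  grid <- gridGeom(nrow(m1), ncol(m1), cellsize)
  arr <- array(0, dim = c(nrow(m1), ncol(m1), length(layers)),
               dimnames = list(NULL, NULL,
                               sprintf("f%02d", seq_along(layers))))
  for (j in seq_along(layers)) arr[, , j] <- layers[[j]]
  if (is.null(weights)) weights <- rep(1, length(layers))
  names(weights) <- dimnames(arr)[[3]]
  new("FeatureStack", grid = grid, features = arr, weights = weights)
}

# row-major 0-based cell-id vector of a matrix
rowMajorVec <- function(m) as.vector(t(m))

# Exhaustive greedy removal oracle: recomputes remaining feature totals from
# scratch every round (independent of the incremental implementation).
# V: n x f value matrix in row-major cell order; returns 0-based removal order.
greedyOracle <- function(V, w, rule = "ABF", protected = NULL) {
  n <- nrow(V)
  alive <- rep(TRUE, n)
  prot <- if (is.null(protected)) rep(FALSE, n) else protected
  ord <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(alive & !prot)
    if (!length(cand)) cand <- which(alive)
    R <- colSums(V[alive, , drop = FALSE])
    loss <- vapply(cand, function(cc) {
      contrib <- ifelse(R > 0, w * V[cc, ] / R, 0)
      if (rule == "ABF") sum(contrib) else max(contrib)
    }, numeric(1))
    pick <- cand[order(loss, cand)][1]
    ord <- c(ord, pick)
    alive[pick] <- FALSE
  }
  ord - 1L
}

# 50-year two-scenario fixture reused by several simulation tests
standardClimate <- function(years = 2015:2064, seed = 1,
                            scenario = "current") {
  generateClimate(scenario, years, seed)
}

baseTargetOf <- function(landscape, fraction = 0.03) {
  seg <- segmentTable(landscape)
  fraction * sum(seg$stem_volume * seg$area_m2 / 1e4)
}
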