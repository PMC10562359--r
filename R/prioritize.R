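# Spatial conservation prioritization: condition penalties, iterative
# representation-balancing cell ranking, regional protection-area selection.

#' Condition-penalty multiplier for managed forest
#'
#' A 0-1 multiplier degrading biodiversity value where forestry has altered
#' naturalness: \code{max(floor, 1 - intensity * decay^yearsSince)}.
#' Monotone non-increasing in management intensity and non-decreasing in
#' years since the last action; untouched cells (intensity 0) get 1.
#'
#' @param intensity management intensity in \[0, 1\] (vectorized).
#' @param yearsSince years since the last management action.
#' @param decay yearly recovery rate in (0, 1).
#' @param floor lowest multiplier.
#' @return multiplier in \[floor, 1\].
#' @export
#' @examples
#' conditionPenalty(1, 0)    # fresh clearcut
#' conditionPenalty(1, 100)  # long recovered
conditionPenalty <- function(intensity, yearsSince, decay = 0.95,
                             floor = 0.1) {
  stopifnot(all(intensity >= 0 & intensity <= 1), all(yearsSince >= 0),
            decay > 0, decay < 1)
  pmax(floor, 1 - intensity * decay^yearsSince)
}

#' Build per-cell penalty surfaces from a landscape
#'
#' Area-weighted management intensity and minimum years-since-action per
#' cell give the base multiplier; the herb-rich deadwood group additionally
#' carries a drainage penalty where drained peat dominates the cell.
#'
#' @param landscape a [Landscape-class].
#' @param decay,floor passed to [conditionPenalty()].
#' @param drainageFactor extra multiplier on the herb-rich deadwood group in
#'   drained-peat-dominated cells.
#' @return list of matrices \code{herbrich_deadwood} and
#'   \code{other_features}.
#' @export
landscapePenalties <- function(landscape, decay = 0.95, floor = 0.1,
                               drainageFactor = 0.7) {
  grid <- gridGeometry(landscape)
  seg <- segmentTable(landscape)
  n <- nCells(grid)
  wInt <- numeric(n); area <- numeric(n); yrs <- rep(Inf, n)
  peatArea <- numeric(n)
  aggI <- rowsum(seg$mgmt_intensity * seg$area_m2, seg$cell_id)
  aggA <- rowsum(seg$area_m2, seg$cell_id)
  ids <- as.integer(rownames(aggA)) + 1L
  wInt[ids] <- aggI[, 1]; area[ids] <- aggA[, 1]
  aggY <- vapply(split(seg$years_since_action, seg$cell_id), min, numeric(1))
  yrs[as.integer(names(aggY)) + 1L] <- aggY
  aggP <- rowsum(seg$area_m2 * (seg$soil == "drained_peat"), seg$cell_id)
  peatArea[ids] <- aggP[, 1]

  intensity <- ifelse(area > 0, wInt / area, 0)
  yrs[!is.finite(yrs)] <- 200
  base <- conditionPenalty(intensity, yrs, decay, floor)
  herb <- base * ifelse(area > 0 & peatArea / pmax(area, 1) > 0.5,
                        drainageFactor, 1)
  list(herbrich_deadwood = .vecToMatrix(herb, grid),
       other_features = .vecToMatrix(base, grid))
}

#' Apply condition penalties to a feature stack
#'
#' Multiplies each feature layer by its group's per-cell multiplier. The
#' herb-rich deadwood penalty group applies only to features mapped to it;
#' all other features take the other-features group.
#'
#' @param features a [FeatureStack-class].
#' @param penalties list of multiplier matrices keyed by group (values in
#'   \[0, 1\], grid-matching).
#' @param featureGroups named character mapping feature names to penalty
#'   groups; unmapped features default to \code{"other_features"}.
#' @return a penalized [FeatureStack-class].
#' @export
applyConditionPenalty <- function(features, penalties,
                                  featureGroups = NULL) {
  grid <- gridGeometry(features)
  for (g in names(penalties)) {
    m <- penalties[[g]]
    if (!identical(dim(m), c(grid@nrow, grid@ncol)))
      stop(sprintf("penalty surface '%s' does not match the feature grid", g),
           call. = FALSE)
    if (any(m < 0 | m > 1))
      stop(sprintf("penalty multipliers in '%s' outside [0, 1]", g),
           call. = FALSE)
  }
  arr <- featureValues(features)
  nms <- featureNames(features)
  for (j in seq_along(nms)) {
    grp <- if (!is.null(featureGroups) && nms[j] %in% names(featureGroups))
      featureGroups[[nms[j]]] else "other_features"
    if (!grp %in% names(penalties))
      stop(sprintf("no penalty surface for group '%s'", grp), call. = FALSE)
    arr[, , j] <- arr[, , j] * penalties[[grp]]
  }
  new("FeatureStack", grid = grid, features = arr,
      weights = featureWeights(features))
}

#' Hierarchical priority ranking by iterative cell removal
#'
#' Ranks every cell by repeatedly removing the least valuable cells while
#' tracking each feature's remaining representation. Marginal loss of cell
#' c is \eqn{\sum_f w_f v_{cf} / R_f} under the additive-benefit rule (ABF)
#' or \eqn{\max_f w_f v_{cf} / R_f} under the core-area rule (CAZ), with
#' \eqn{R_f} the remaining total of feature f. Each round removes the
#' \code{warp} lowest-loss cells (ties broken by row-major cell index, so
#' the ranking is deterministic). Cells under the protected mask are removed
#' last, giving them the highest ranks: the ranking identifies priority
#' forest that best complements the existing reserve network. Features with
#' zero total are dropped with a warning.
#'
#' @param features a [FeatureStack-class].
#' @param rule "ABF" (default) or "CAZ".
#' @param protectedMask optional logical matrix on the feature grid.
#' @param warp cells removed per round (1 for exact ranking; larger is
#'   faster and coarser, standard practice for big grids).
#' @param weights optional positive per-feature weights; defaults to the
#'   stack's.
#' @return a [PriorityRanking-class]; ranks in (0, 1], 1 = removed last.
#' @export
rankCells <- function(features, rule = c("ABF", "CAZ"),
                      protectedMask = NULL, warp = 1L, weights = NULL) {
  rule <- match.arg(rule)
  grid <- gridGeometry(features)
  n <- nCells(grid)
  warp <- max(1L, as.integer(warp))
  if (is.null(weights)) weights <- featureWeights(features)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)

  arr <- featureValues(features)
  nf <- dim(arr)[3]
  V <- vapply(seq_len(nf),
              function(j) .matrixToVec(arr[, , j], grid), numeric(n))
  R0 <- colSums(V)
  keep <- R0 > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d feature(s) with zero total: %s",
                    sum(!keep),
                    paste(featureNames(features)[!keep], collapse = ", ")))
    V <- V[, keep, drop = FALSE]
    weights <- weights[keep]
    R0 <- R0[keep]
  }
  if (!ncol(V)) stop("no features with positive total", call. = FALSE)
  colnames(V) <- featureNames(features)[keep]
  names(R0) <- colnames(V)

  protVec <- if (is.null(protectedMask)) rep(FALSE, n) else {
    if (!identical(dim(protectedMask), c(grid@nrow, grid@ncol)))
      stop("protected mask does not match the feature grid", call. = FALSE)
    .matrixToVec(protectedMask, grid)
  }

  R <- R0
  alive <- rep(TRUE, n)
  removal <- integer(n)
  nRemoved <- 0L
  repRows <- list(data.frame(fraction_removed = 0,
                             t(stats::setNames(rep(1, length(R0)),
                                               colnames(V)))))

  # two hierarchy tiers: unprotected cells are exhausted first
  for (tier in list(which(!protVec), which(protVec))) {
    tierAlive <- intersect(tier, which(alive))
    while (length(tierAlive)) {
      invR <- ifelse(R > 0, 1 / R, 0)
      Vt <- V[tierAlive, , drop = FALSE]
      loss <- if (rule == "ABF") {
        as.numeric(Vt %*% (weights * invR))
      } else {
        l <- rep(0, length(tierAlive))
        for (j in seq_along(R))
          l <- pmax(l, weights[j] * Vt[, j] * invR[j])
        l
      }
      take <- utils::head(order(loss, tierAlive), warp)
      cells <- tierAlive[take]
      removal[nRemoved + seq_along(cells)] <- cells
      nRemoved <- nRemoved + length(cells)
      R <- R - colSums(V[cells, , drop = FALSE])
      alive[cells] <- FALSE
      tierAlive <- tierAlive[-take]
      repRows[[length(repRows) + 1L]] <-
        data.frame(fraction_removed = nRemoved / n,
                   t(pmax(0, R) / R0))
    }
  }

  rank <- numeric(n)
  rank[removal] <- seq_len(n) / n
  rep <- do.call(rbind, repRows)
  names(rep) <- c("fraction_removed", colnames(V))
  new("PriorityRanking", grid = grid,
      rank = .vecToMatrix(rank, grid),
      removalOrder = as.integer(removal - 1L),
      representation = rep, rule = rule, warp = as.integer(warp))
}

#' Select regional protection areas from a national ranking
#'
#' For each region, adds unprotected forest cells in descending national
#' rank until the protected forest area reaches \code{targetFraction} of the
#' region's forest area (or land area, by the denominator switch). Regions
#' already at the target get no additions; regions without enough forest are
#' filled best-effort and flagged.
#'
#' @param ranking a [PriorityRanking-class] (national).
#' @param landscape the matching [Landscape-class].
#' @param targetFraction protection target (default 0.10).
#' @param denominator "forest" (default): target counted against forest
#'   area; "land": against total land area.
#' @return list with \code{mask} (logical matrix of new protection cells)
#'   and \code{summary} (data.frame per region: target, existing and added
#'   protected area in km2, added fraction, and whether the target was
#'   reached).
#' @export
selectProtectionAreas <- function(ranking, landscape, targetFraction = 0.10,
                                  denominator = c("forest", "land")) {
  denominator <- match.arg(denominator)
  grid <- gridGeometry(landscape)
  .assertSameGrid(grid, gridGeometry(ranking), "landscape and ranking")
  seg <- segmentTable(landscape)
  n <- nCells(grid)

  forestArea <- numeric(n)
  agg <- rowsum(seg$area_m2, seg$cell_id)
  forestArea[as.integer(rownames(agg)) + 1L] <- agg[, 1]

  rankVec <- .matrixToVec(rankSurface(ranking), grid)
  protVec <- .matrixToVec(protectedMask(landscape), grid)
  regVec <- .matrixToVec(regionMap(landscape) + 0, grid)

  rg <- regionTable(landscape)
  newMask <- rep(FALSE, n)
  rows <- list()
  for (i in seq_len(nrow(rg))) {
    rid <- rg$region_id[i]
    inRegion <- regVec == rid
    denomArea <- if (denominator == "forest") {
      sum(forestArea[inRegion])
    } else rg$land_area_km2[i] * 1e6
    target <- targetFraction * denomArea
    existing <- sum(forestArea[inRegion & protVec])
    cand <- which(inRegion & !protVec & forestArea > 0)
    cand <- cand[order(-rankVec[cand], cand)]
    added <- 0
    j <- 0L
    while (existing + added < target && j < length(cand)) {
      j <- j + 1L
      newMask[cand[j]] <- TRUE
      added <- added + forestArea[cand[j]]
    }
    rows[[i]] <- data.frame(
      region_id = rid,
      target_km2 = target / 1e6,
      existing_km2 = existing / 1e6,
      added_km2 = added / 1e6,
      added_fraction = if (denomArea > 0) added / denomArea else 0,
      cells_added = sum(newMask[inRegion]),
      reached = existing + added >= target - 1e-9)
  }
  list(mask = .vecToMatrix(as.numeric(newMask), grid) > 0,
       summary = do.call(rbind, rows))
}

#' Feature representation captured by a mask
#'
#' Fraction of each feature's total value lying inside a mask (e.g. the
#' top-ranked 10% of the landscape, or a protection-area selection).
#'
#' @param features a [FeatureStack-class].
#' @param mask logical matrix on the feature grid.
#' @return named numeric, captured fraction per feature.
#' @export
representationReport <- function(features, mask) {
  grid <- gridGeometry(features)
  if (!identical(dim(mask), c(grid@nrow, grid@ncol)))
    stop("mask does not match the feature grid", call. = FALSE)
  arr <- featureValues(features)
  vapply(seq_len(dim(arr)[3]), function(j) {
    tot <- sum(arr[, , j])
    if (tot == 0) return(0)
    sum(arr[, , j][mask]) / tot
  }, numeric(1)) |> stats::setNames(featureNames(features))
}

#' Top-ranked fraction mask
#'
#' @param ranking a [PriorityRanking-class].
#' @param fraction fraction of highest-ranked cells (default 0.10).
#' @return logical matrix marking the top-ranked cells.
#' @export
topFractionMask <- function(ranking, fraction = 0.10) {
  r <- rankSurface(ranking)
  r > 1 - fraction + 1e-12
}
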