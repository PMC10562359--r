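test_that("condition penalties are monotone and bounded", {
  expect_equal(conditionPenalty(0, 0), 1)      # untouched
  expect_gte(conditionPenalty(1, 0), 0.1)
  # non-increasing in intensity
  expect_true(all(diff(conditionPenalty(seq(0, 1, 0.1), 5)) <= 0))
  # non-decreasing in years since action
  expect_true(all(diff(conditionPenalty(0.8, 0:100)) >= 0))
  # recent clearcut scores lower than century-old recovery
  expect_lt(conditionPenalty(1, 1), conditionPenalty(1, 100))
})

test_that("penalty application scales features groupwise", {
  set.seed(23)
  layers <- list(matrix(stats::runif(16), 4), matrix(stats::runif(16), 4))
  fs <- makeStack(layers)
  ones <- matrix(1, 4, 4)
  pen <- list(herbrich_deadwood = ones * 0.5, other_features = ones)

  # all-ones multipliers leave the stack unchanged
  same <- applyConditionPenalty(fs, list(herbrich_deadwood = ones,
                                         other_features = ones))
  expect_equal(featureValues(same), featureValues(fs))

  # group mapping: only the mapped feature is scaled
  out <- applyConditionPenalty(fs, pen,
                               featureGroups = c(f01 = "herbrich_deadwood"))
  expect_equal(featureValues(out)[, , 1], 0.5 * layers[[1]])
  expect_equal(featureValues(out)[, , 2], layers[[2]])

  # zero multiplier zeroes all feature values in that cell
  pz <- list(other_features = ones)
  pz$other_features[2, 3] <- 0
  outz <- applyConditionPenalty(fs, pz)
  expect_true(all(featureValues(outz)[2, 3, ] == 0))

  bad <- list(other_features = ones * 1.5)
  expect_error(applyConditionPenalty(fs, bad), "outside")
})

test_that("single-feature ranking removes in ascending value order", {
  m <- matrix(c(5, 1, 8, 3, 9, 2, 7, 4, 6), 3, 3, byrow = TRUE)
  fs <- makeStack(list(m))
  rk <- rankCells(fs, "ABF", warp = 1)
  expect_equal(removalOrder(rk), order(rowMajorVec(m)) - 1L)
  # rank bijectivity
  r <- sort(rowMajorVec(rankSurface(rk)))
  expect_equal(r, (1:9) / 9)
})

test_that("identical cells give the diagonal representation curve", {
  fs <- makeStack(list(matrix(1, 4, 4), matrix(2, 4, 4)))
  rk <- rankCells(fs, "ABF", warp = 1)
  rep <- representationCurves(rk)
  expect_equal(rep$f01, 1 - rep$fraction_removed, tolerance = 1e-12)
  expect_true(all(diff(rep$f01) <= 1e-12))   # non-increasing
  expect_equal(utils::tail(rep$f01, 1), 0)
})

test_that("ranking equals the exhaustive greedy oracle on small grids", {
  set.seed(41)
  for (rule in c("ABF", "CAZ")) {
    for (rep_i in 1:6) {
      nr <- sample(2:5, 1); nc <- sample(2:5, 1)
      nf <- sample(1:3, 1)
      layers <- replicate(nf, matrix(stats::runif(nr * nc), nr, nc),
                          simplify = FALSE)
      fs <- makeStack(layers)
      rk <- rankCells(fs, rule, warp = 1)
      V <- vapply(layers, rowMajorVec, numeric(nr * nc))
      expect_equal(removalOrder(rk),
                   greedyOracle(V, rep(1, nf), rule),
                   info = sprintf("%s %dx%d f=%d", rule, nr, nc, nf))
    }
  }
})

test_that("protected cells are removed last and top-k sets nest", {
  set.seed(43)
  layers <- list(matrix(stats::runif(36), 6), matrix(stats::runif(36), 6))
  fs <- makeStack(layers)
  prot <- matrix(FALSE, 6, 6); prot[1:2, 1:3] <- TRUE
  rk <- rankCells(fs, "ABF", protectedMask = prot, warp = 1)
  ranks <- rankSurface(rk)
  expect_true(min(ranks[prot]) > max(ranks[!prot]))

  # oracle agreement with the protection hierarchy
  V <- vapply(layers, rowMajorVec, numeric(36))
  expect_equal(removalOrder(rk),
               greedyOracle(V, c(1, 1), "ABF", rowMajorVec(prot)))

  # nestedness of top-k sets for fixed warp
  ord <- removalOrder(rk)
  for (k in c(5, 10, 20)) {
    topK <- utils::tail(ord, k)
    topK2 <- utils::tail(ord, k + 1)
    expect_true(all(topK %in% topK2))
  }

  # penalty neutrality: all-ones penalty leaves the ranking identical
  ones <- matrix(1, 6, 6)
  fsPen <- applyConditionPenalty(fs, list(other_features = ones))
  expect_identical(removalOrder(rankCells(fsPen, "ABF", warp = 1)),
                   removalOrder(rankCells(fs, "ABF", warp = 1)))
})

test_that("zero-total features are dropped with a warning", {
  fs <- makeStack(list(matrix(stats::runif(9), 3), matrix(0, 3, 3)))
  expect_warning(rk <- rankCells(fs, "ABF", warp = 1), "zero total")
  expect_length(removalOrder(rk), 9)
})

test_that("regional selection fills to target on national rank order", {
  ls <- tinyLandscape(seed = 13, nRegions = 3, nrow = 20, ncol = 20)
  fs <- generateBdFeatures(ls, 4, autocorrRange = 3, seed = 13)
  rk <- rankCells(fs, "ABF", protectedMask = protectedMask(ls), warp = 2)
  sel <- selectProtectionAreas(rk, ls, targetFraction = 0.10)
  s <- sel$summary

  # every region reaches (or already exceeded) the target
  expect_true(all(s$reached))
  # a region already above target receives zero cells
  over <- s$existing_km2 >= s$target_km2
  expect_true(all(s$cells_added[over] == 0))
  # added cells are each region's own top-ranked unprotected forest cells
  grid <- gridGeometry(ls)
  rankVec <- rowMajorVec(rankSurface(rk))
  protVec <- rowMajorVec(protectedMask(ls))
  regVec <- rowMajorVec(regionMap(ls))
  selVec <- rowMajorVec(sel$mask)
  seg <- segmentTable(ls)
  hasForest <- logical(length(rankVec))
  hasForest[unique(seg$cell_id) + 1] <- TRUE
  for (rid in s$region_id[!over]) {
    inR <- regVec == rid & !protVec & hasForest
    chosen <- which(selVec & inR)
    notChosen <- which(inR & !selVec)
    if (length(chosen) && length(notChosen))
      expect_gte(min(rankVec[chosen]), max(rankVec[notChosen]) - 1e-12)
  }
})

test_that("top-ranked selection out-represents random selections", {
  ls <- tinyLandscape(seed = 19, nrow = 14, ncol = 14)
  fs <- generateBdFeatures(ls, 3, autocorrRange = 3, seed = 19)
  rk <- rankCells(fs, "ABF", warp = 1)
  top <- topFractionMask(rk, 0.10)
  minTop <- min(representationReport(fs, top))
  n <- nCells(gridGeometry(fs))
  k <- sum(top)
  set.seed(77)
  wins <- 0
  for (i in 1:100) {
    rnd <- matrix(FALSE, 14, 14)
    rnd[sample(n, k)] <- TRUE
    if (minTop >= min(representationReport(fs, rnd))) wins <- wins + 1
  }
  expect_gte(wins, 95)

  # boundary masks
  expect_equal(unname(representationReport(fs, matrix(TRUE, 14, 14))),
               rep(1, 3))
  expect_equal(unname(representationReport(fs, matrix(FALSE, 14, 14))),
               rep(0, 3))
})
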