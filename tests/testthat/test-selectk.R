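test_that("well-separated blobs produce a near-unanimous correct vote", {
  blobs <- makeBlobs(15, rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0)),
                     sdWithin = 0.3, seed = 2)
  sol <- selectKMajority(blobs$x, kRange = 2:6, seed = 1, nInit = 20,
                         gapRefs = 20)
  expect_equal(chosenK(sol), 3L)
  tally <- voteTally(sol)
  expect_gte(tally[["3"]], 9)
  expect_equal(adjustedRand(clusterLabels(sol), blobs$labels), 1)
})

test_that("chosen k is invariant to feature order and subject order", {
  blobs <- makeBlobs(20, rbind(c(0, 0), c(6, 6)), sdWithin = 0.4, seed = 3)
  sol <- selectKMajority(blobs$x, kRange = 2:5, seed = 4, nInit = 20,
                         gapRefs = 15)
  # column permutation leaves distances untouched: identical selection
  solCol <- selectKMajority(blobs$x[, 2:1], kRange = 2:5, seed = 4,
                            nInit = 20, gapRefs = 15)
  expect_equal(chosenK(solCol), chosenK(sol))
  expect_equal(clusterLabels(solCol), clusterLabels(sol))
  # all deterministic criteria are bitwise equal; the gap statistic's
  # uniform reference draws depend on column order, so it is compared at
  # the vote level instead
  det <- setdiff(rownames(criteriaValues(sol)), "gap")
  expect_equal(criteriaValues(solCol)[det, ], criteriaValues(sol)[det, ])
  expect_equal(indexVotes(solCol)[det], indexVotes(sol)[det])
  # row permutation: same chosen k on clearly separated data
  set.seed(9)
  perm <- sample(nrow(blobs$x))
  solRow <- selectKMajority(blobs$x[perm, ], kRange = 2:5, seed = 4,
                            nInit = 20, gapRefs = 15)
  expect_equal(chosenK(solRow), chosenK(sol))
  expect_equal(adjustedRand(clusterLabels(solRow),
                            clusterLabels(sol)[perm]), 1)
})

test_that("plurality ties break toward the smaller k", {
  # two identical four-blob arms: k = 2 and k = 4 both plausible; whatever
  # the tally, the winner must be a modal k and ties must pick the smaller
  blobs <- makeBlobs(12, rbind(c(0, 0), c(0, 4), c(10, 0), c(10, 4)),
                     sdWithin = 0.3, seed = 5)
  sol <- selectKMajority(blobs$x, kRange = 2:6, seed = 2, nInit = 20,
                         gapRefs = 15)
  tally <- voteTally(sol)
  modal <- as.integer(names(tally)[tally == max(tally)])
  expect_equal(chosenK(sol), min(modal))
})

makeToyFeatures <- function(seed = 13) {
  cfg <- smallConfig(seed = seed)
  grid <- smallGrid(30L)
  masks <- generateMasks(grid)
  cohort <- generateCohort(cfg)
  conn <- cohortConnectivity(cohort, masks, grid, cfg)
  buildFeatureMatrix(cohort, conn)
}

test_that("deviance ordering puts the high-SSPG/leptin cluster first and is canonical", {
  fm <- makeToyFeatures()
  x <- scaledFeatures(fm)
  fit <- kmeansFit(x, 2, seed = 1, nInit = 10)
  mkSol <- function(labels) new("ClusterSolution",
    kRange = 2L, criteria = matrix(0, 1, 1), orientation = "max",
    votes = c(ch = 2L), tally = c(`2` = 1L), chosenK = 2L,
    labels = labels, centroids = fit$centers,
    withinSS = fit$wss, wssByK = fit$wss, devianceOrdered = FALSE)
  sol <- orderByDeviance(mkSol(fit$labels), fm)
  z <- x[, c("SSPG", "leptin")]
  lab <- clusterLabels(sol)
  expect_gt(mean(z[lab == 1, ]), mean(z[lab == 2, ]))
  # permuting the input labels yields the identical canonical labeling
  solSwap <- orderByDeviance(mkSol(3L - fit$labels), fm)
  expect_equal(clusterLabels(solSwap), lab)
})

test_that("metabolic-only clustering uses the 7 blood-based features", {
  fm <- makeToyFeatures(seed = 19)
  expect_equal(ncol(scaledFeatures(fm, "metabolic")), 7)
  sol <- clusterMetabolicOnly(fm, kRange = 2:4, seed = 1, nInit = 10,
                              gapRefs = 10)
  expect_s4_class(sol, "ClusterSolution")
  expect_true(chosenK(sol) %in% 2:4)
  expect_equal(length(clusterLabels(sol)), ncol(fm))
})

test_that("single-feature input still runs the index suite", {
  set.seed(30)
  x <- matrix(c(rnorm(15), rnorm(15, 6)), ncol = 1)
  sol <- selectKMajority(x, kRange = 2:4, seed = 1, nInit = 10,
                         gapRefs = 10)
  expect_equal(chosenK(sol), 2L)
})
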