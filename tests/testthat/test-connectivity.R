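test_that("fisherZ is the clipped atanh: odd, monotone, finite at |r| = 1", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisherZ(-0.5), -fisherZ(0.5))
  expect_equal(fisherZ(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisherZ(1)) && fisherZ(1) > 8)
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_error(fisherZ(1.01), "domain error")
})

test_that("cohesiveness handles identity, null and degenerate inputs", {
  T <- 50
  one <- matrix(rep(sin(1:T), 4), 4, T, byrow = TRUE)
  expect_equal(cohesiveness(one), atanh(1 - 1e-7))
  set.seed(9)
  noise <- matrix(rnorm(40 * 400), 40, 400)
  expect_lt(abs(cohesiveness(noise)), 3 / sqrt(400))
  expect_error(cohesiveness(matrix(1:5, 1)), "at least 2 voxels")
})

test_that("cohesiveness is invariant to voxel order and positive affine rescaling", {
  set.seed(3)
  X <- matrix(rnorm(30 * 80), 30, 80) + rep(rnorm(80), each = 30)
  z <- cohesiveness(X)
  expect_equal(cohesiveness(X[sample(30), ]), z)
  expect_equal(cohesiveness(3.7 * X + 11), z, tolerance = 1e-10)
  # pairwise variant shares the invariances
  zp <- cohesiveness(X, method = "pairwise")
  expect_equal(cohesiveness(2 * X[sample(30), ] - 5, method = "pairwise"),
               zp, tolerance = 1e-10)
})

test_that("cohesiveness matches the equicorrelated closed form", {
  rho <- 0.3; V <- 100; T <- 200
  set.seed(11)
  zs <- vapply(1:30, function(i) {
    s <- rnorm(T)
    X <- sqrt(rho) * matrix(s, V, T, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(V * T), V, T)
    cohesiveness(X)
  }, 0)
  target <- atanh(expectedCohesivenessR(rho, V))  # ~0.602
  se <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs) - target), 3 * se + 0.005)
})

test_that("integration is the Fisher-Z of the mean-series correlation", {
  set.seed(5)
  seg <- matrix(rnorm(10 * 100), 10, 100)
  expect_equal(integrationZ(seg, seg), atanh(1 - 1e-7))
  other <- matrix(rnorm(8 * 100), 8, 100)
  expect_equal(integrationZ(seg, other),
               fisherZ(cor(colMeans(seg), colMeans(other))))
  expect_error(integrationZ(seg, other[, 1:50]), "shape error")
})

test_that("connectivity profile has the 18 canonical features and L/R symmetry", {
  cfg <- smallConfig(seed = 21)
  grid <- smallGrid(40L)
  masks <- generateMasks(grid)
  cohort <- filterComplete(generateCohort(cfg))
  series <- simulateRoiSeries(cohort[1, ], masks, grid, cfg)
  prof <- connectivityProfile(masks = masks, series = series)
  expect_named(prof, connectivityFeatureNames())
  expect_true(all(is.finite(prof)))
  # swapping the left/right inputs swaps the lateralized features
  swapped <- series
  for (nm in c("hipp", "DG", "CA1sub")) {
    swapped[[paste0("L_", nm)]] <- series[[paste0("R_", nm)]]
    swapped[[paste0("R_", nm)]] <- series[[paste0("L_", nm)]]
  }
  profSw <- connectivityProfile(masks = masks, series = swapped)
  expect_equal(profSw[["coh_L"]], prof[["coh_R"]])
  expect_equal(profSw[["L_post_CEN"]], prof[["R_post_CEN"]])
  expect_equal(profSw[["R_ant_VIS"]], prof[["L_ant_VIS"]])
})

test_that("cluster 1 shows lower cohesiveness and integration on every feature", {
  cfg <- defaultCohortConfig(nEnrolled = 60L, nComplete = 60L,
                             clusterSizes = c(30L, 30L), seed = 17)
  grid <- defaultGridSpec()
  masks <- generateMasks(grid)
  cohort <- generateCohort(cfg)
  conn <- cohortConnectivity(cohort, masks, grid, cfg)
  lat <- filterComplete(cohort)$latent_cluster
  feats <- as.matrix(conn[, connectivityFeatureNames()])
  gap <- colMeans(feats[lat == 2, ]) - colMeans(feats[lat == 1, ])
  expect_true(all(gap > 0))
})
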