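test_that("mask set has nested segments, disjoint lateralized ROIs and valid sizes", {
  masks <- generateMasks(defaultGridSpec())
  sz <- maskSizes(masks)
  expect_true(all(sz > 0))
  expect_gte(sz[["L_hipp"]], 50)
  expect_gte(sz[["R_hipp"]], 50)
  arr <- function(n) getMask(masks, n)@data
  # segments nested in their hippocampus, disjoint from each other
  for (side in c("L", "R")) {
    hip <- arr(paste0(side, "_hipp"))
    dg <- arr(paste0(side, "_DG")); ca <- arr(paste0(side, "_CA1sub"))
    expect_true(all(hip[dg]))
    expect_true(all(hip[ca]))
    expect_false(any(dg & ca))
    # partition arithmetic: remainder is non-negative
    expect_gte(sum(hip) - sum(dg) - sum(ca), 0)
  }
  expect_false(any(arr("L_hipp") & arr("R_hipp")))
  # RSNs disjoint from hippocampi and from each other
  rsn <- c("CEN", "SAL", "VIS", "SMN")
  for (n in rsn) {
    expect_false(any(arr(n) & (arr("L_hipp") | arr("R_hipp"))))
    for (m in setdiff(rsn, n)) expect_false(any(arr(n) & arr(m)))
  }
})

test_that("too-small grids are rejected", {
  expect_error(generateMasks(gridSpec(dims = c(10, 10, 6))), "too small")
})

test_that("ROI series simulation is deterministic and order-independent per subject", {
  cfg <- smallConfig(seed = 11)
  grid <- smallGrid()
  masks <- generateMasks(grid)
  cohort <- filterComplete(generateCohort(cfg))
  s1 <- simulateRoiSeries(cohort[1, ], masks, grid, cfg)
  s2 <- simulateRoiSeries(cohort[2, ], masks, grid, cfg)
  # regenerating subject 1 after subject 2 is bitwise identical
  expect_identical(simulateRoiSeries(cohort[1, ], masks, grid, cfg), s1)
  expect_false(identical(s1$L_hipp, s2$L_hipp))
  # segments are row subsets of their hippocampus
  expect_equal(dim(s1$L_DG), c(sum(getMask(masks, "L_DG")@data),
                               grid@nTimepoints))
})

test_that("subjects without a latent cluster cannot be simulated", {
  cfg <- smallConfig()
  grid <- smallGrid()
  masks <- generateMasks(grid)
  expect_error(
    simulateRoiSeries(list(subject_id = "X", latent_cluster = NA),
                      masks, grid, cfg),
    "latent cluster")
})

test_that("zero within-ROI correlation gives uncorrelated voxels", {
  cfg <- smallConfig(rhoWithin = c(0, 0), rhoLogitSd = 0)
  grid <- smallGrid(200L)
  masks <- generateMasks(grid)
  cohort <- filterComplete(generateCohort(cfg))
  s <- simulateRoiSeries(cohort[1, ], masks, grid, cfg)
  C <- cor(t(s$L_hipp))
  expect_lt(abs(mean(C[upper.tri(C)])), 3 / sqrt(grid@nTimepoints))
})

test_that("equicorrelated factor model matches its closed forms", {
  # leave-one-out voxel correlation: rho sqrt((V-1)/(1+(V-2) rho))
  rho <- 0.3; V <- 100; T <- 200
  expect_equal(expectedCohesivenessR(rho, V), 0.5414, tolerance = 1e-3)
  set.seed(42)
  reps <- 40
  rbar <- vapply(seq_len(reps), function(i) {
    s <- rnorm(T)
    X <- sqrt(rho) * matrix(s, V, T, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(V * T), V, T)
    mean(vapply(seq_len(V), function(v)
      cor(X[v, ], colMeans(X[-v, ])), 0))
  }, 0)
  se <- sd(rbar) / sqrt(reps)
  expect_lt(abs(mean(rbar) - expectedCohesivenessR(rho, V)), 3 * se)
})

test_that("segment-network coupling matches the averaging-attenuation closed form", {
  # corr(segment mean, network generator) -> rho_c * sqrt(V rho_w / (1+(V-1) rho_w))
  cfg <- smallConfig(rhoWithin = c(0.3, 0.3), rhoCross = c(0.6, 0.6),
                     rhoRsn = 0.999, rhoLogitSd = 0)
  grid <- smallGrid(200L)
  masks <- generateMasks(grid)
  cohort <- filterComplete(generateCohort(cfg))
  Vseg <- sum(getMask(masks, "L_DG")@data)
  target <- 0.6 * averagingAttenuation(0.3, Vseg)
  rs <- vapply(seq_len(nrow(cohort)), function(i) {
    s <- simulateRoiSeries(cohort[i, ], masks, grid, cfg)
    cor(colMeans(s$L_DG), colMeans(s$CEN))
  }, 0)
  se <- sd(rs) / sqrt(length(rs))
  expect_lt(abs(mean(rs) - target), 4 * se + 0.01)
})

test_that("volume embedding reproduces the ROI series under extraction", {
  cfg <- smallConfig(seed = 5)
  grid <- smallGrid(20L)
  masks <- generateMasks(grid)
  cohort <- filterComplete(generateCohort(cfg))
  vol <- simulateBoldVolume(cohort[1, ], masks, grid, cfg)
  series <- simulateRoiSeries(cohort[1, ], masks, grid, cfg)
  for (nm in c("L_hipp", "R_DG", "SAL"))
    expect_equal(extractRoiTimeseries(vol, getMask(masks, nm)),
                 series[[nm]], ignore_attr = TRUE)
})
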