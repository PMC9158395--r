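test_that("cohort has the designed enrollment, completeness and cluster structure", {
  cfg <- defaultCohortConfig()
  cohort <- generateCohort(cfg)
  expect_equal(nrow(cohort), 126)
  complete <- filterComplete(cohort)
  expect_equal(nrow(complete), 104)
  expect_equal(unname(table(complete$latent_cluster)), c(51L, 53L),
               ignore_attr = TRUE)
  # unmeasured values are NA exactly where a modality is missing
  expect_true(all(is.na(cohort$SSPG[!cohort$has_ist])))
  expect_true(all(is.na(cohort$motion_mean_mm[!cohort$has_imaging])))
  expect_true(all(!is.na(complete$SSPG)))
  # physiological positivity and motion ordering
  num <- c("age", "BMI", "WC", "SSPG", "FPI", "FPG", "leptin", "cortisol")
  expect_true(all(as.matrix(complete[, num]) > 0))
  expect_true(all(complete$motion_max_mm >= complete$motion_mean_mm))
})

test_that("generation is deterministic given the seed", {
  cfg <- defaultCohortConfig(seed = 7)
  expect_identical(generateCohort(cfg), generateCohort(cfg))
  cfg2 <- defaultCohortConfig(seed = 8)
  expect_false(identical(generateCohort(cfg), generateCohort(cfg2)))
})

test_that("cluster-1 SSPG marginal mean is calibrated within Monte-Carlo error", {
  cfg <- defaultCohortConfig()
  means <- vapply(1:200, function(s) {
    cfg@seed <- as.integer(1000 + s)
    co <- filterComplete(generateCohort(cfg))
    mean(co$SSPG[co$latent_cluster == 1])
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - cfg@clusterMeans["cluster1", "SSPG"]), 3 * se)
})

test_that("no planted effect means no between-cluster SSPG difference", {
  m <- defaultCohortConfig()@clusterMeans["cluster2", , drop = FALSE]
  s <- defaultCohortConfig()@clusterSds["cluster2", , drop = FALSE]
  cfg <- defaultCohortConfig(
    clusterMeans = rbind(cluster1 = m[1, ], cluster2 = m[1, ]),
    clusterSds = rbind(cluster1 = s[1, ], cluster2 = s[1, ]))
  tstats <- vapply(1:30, function(sd_) {
    cfg@seed <- as.integer(2000 + sd_)
    co <- filterComplete(generateCohort(cfg))
    unname(t.test(SSPG ~ latent_cluster, data = co)$statistic)
  }, 0)
  expect_gte(sum(abs(tstats) < 2), 25)
})

test_that("a larger planted SSPG gap yields a larger between-cluster t statistic", {
  meanT <- function(gap) {
    cfg <- defaultCohortConfig()
    cfg@clusterMeans["cluster1", "SSPG"] <-
      cfg@clusterMeans["cluster2", "SSPG"] + gap
    mean(vapply(1:20, function(s) {
      cfg@seed <- as.integer(3000 + s)
      co <- filterComplete(generateCohort(cfg))
      abs(unname(t.test(SSPG ~ latent_cluster, data = co)$statistic))
    }, 0))
  }
  expect_lt(meanT(10), meanT(40))
  expect_lt(meanT(40), meanT(90))
})

test_that("invalid configurations are rejected with informative errors", {
  R <- defaultCohortConfig()@metabolicCor
  R[1, 2] <- 0.2  # asymmetric
  expect_error(defaultCohortConfig(metabolicCor = R), "symmetric")
  R2 <- matrix(0.99, 7, 7) * (1 - diag(7)) + diag(7)
  R2[1, 2] <- R2[2, 1] <- -0.99  # indefinite
  expect_error(defaultCohortConfig(metabolicCor = R2),
               "positive semi-definite")
  expect_error(defaultCohortConfig(clusterSizes = c(50L, 53L)),
               "summing to nComplete")
  expect_error(defaultCohortConfig(rhoWithin = c(1.2, 0.3)), "rho")
})

test_that("cohort CSV round-trips", {
  cohort <- generateCohort(smallConfig(seed = 3))
  path <- tempfile(fileext = ".csv")
  writeCohort(cohort, path)
  back <- readCohort(path)
  expect_equal(back$SSPG, cohort$SSPG)
  expect_equal(as.character(back$sex), as.character(cohort$sex))
})
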