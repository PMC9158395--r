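#' Generate a synthetic study cohort
#'
#' Draws `nEnrolled` subject records with the planted two-cluster structure.
#' The metabolic block (BMI, WC, SSPG, FPI, FPG, leptin, cortisol) is drawn
#' per cluster from a Gaussian copula with zero-truncated normal marginals
#' whose latent means are calibrated so that each realized marginal mean
#' equals the configured cluster mean exactly; the copula correlation is the
#' configured metabolic correlation matrix. Demographics, cognition and head
#' motion are cluster-invariant except for the female fraction.
#'
#' Completeness is deterministic: the first `nComplete` subjects have both
#' neuroimaging and insulin-suppression-test (IST) data; the remaining
#' subjects cycle through missing-imaging / missing-IST / missing-both.
#' SSPG is `NA` without the IST; motion summaries are `NA` without imaging.
#'
#' @param config a [CohortConfig-class].
#' @return `data.frame` with one row per enrolled subject: `subject_id`,
#'   demographics, the metabolic panel, cognitive scores, motion summaries,
#'   `has_imaging`/`has_ist` flags and the planted `latent_cluster`.
#' @examples
#' cohort <- generateCohort(defaultCohortConfig())
#' nrow(cohort)                       # 126 enrolled
#' sum(cohort$has_imaging & cohort$has_ist)  # 104 complete
#' @seealso [filterComplete()], [simulateRoiSeries()]
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  withSeed(config@seed, {
    n <- config@nEnrolled
    nc <- config@nComplete
    ninc <- n - nc
    id <- sprintf("S%03d", seq_len(n))

    hasImaging <- rep(TRUE, n)
    hasIst <- rep(TRUE, n)
    if (ninc > 0) {
      patt <- (seq_len(ninc) - 1L) %% 3L  # 0: no imaging, 1: no IST, 2: neither
      hasImaging[nc + which(patt != 1L)] <- FALSE
      hasIst[nc + which(patt != 0L)] <- FALSE
    }

    cluster <- integer(n)
    cluster[seq_len(nc)] <- sample(rep(1:2, config@clusterSizes))
    if (ninc > 0) cluster[(nc + 1L):n] <- rep_len(1:2, ninc)

    p <- length(config@metabolicVars)
    metab <- matrix(NA_real_, n, p, dimnames = list(NULL, config@metabolicVars))
    for (cl in 1:2) {
      rows <- which(cluster == cl)
      mu <- config@clusterMeans[cl, ]
      sg <- config@clusterSds[cl, ]
      muLat <- vapply(seq_len(p),
                      function(j) trunc0LatentMean(mu[j], sg[j]), 0)
      Z <- MASS::mvrnorm(length(rows), rep(0, p), config@metabolicCor)
      if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
      for (j in seq_len(p))
        metab[rows, j] <- qtrunc0(pnorm(Z[, j]), muLat[j], sg[j])
    }

    sex <- ifelse(runif(n) < config@femaleFraction[cluster],
                  "female", "male")
    ethnicity <- sample(config@ethnicityLevels, n, replace = TRUE,
                        prob = config@ethnicityProbs)
    age <- qtrunc0(runif(n), config@ageMean, config@ageSd)
    iq <- qtrunc0(runif(n), config@iqMean, config@iqSd)
    memP <- qtrunc0(runif(n), config@memoryMeans["pairing"],
                    config@memorySds["pairing"])
    memR <- qtrunc0(runif(n), config@memoryMeans["recall"],
                    config@memorySds["recall"])
    motMean <- rlnorm(n, config@motionMeanlog, config@motionSdlog)
    motMax <- motMean * (1 + rlnorm(n, config@motionMaxExcessMeanlog,
                                    config@motionMaxExcessSdlog))

    out <- data.frame(
      subject_id = id, age = age,
      sex = factor(sex, levels = c("female", "male")),
      ethnicity = factor(ethnicity, levels = config@ethnicityLevels),
      metab,
      IQ = iq, memory_pairing = memP, memory_recall = memR,
      motion_mean_mm = motMean, motion_max_mm = motMax,
      has_imaging = hasImaging, has_ist = hasIst,
      latent_cluster = cluster,
      stringsAsFactors = FALSE)
    out$SSPG[!out$has_ist] <- NA_real_
    out$motion_mean_mm[!out$has_imaging] <- NA_real_
    out$motion_max_mm[!out$has_imaging] <- NA_real_
    out
  })
}

#' Keep subjects with both neuroimaging and IST data
#'
#' @param cohort cohort table from [generateCohort()] (or real data with the
#'   same completeness flags).
#' @return the complete-case subset, rows in original order.
#' @export
filterComplete <- function(cohort) {
  stopifnot(all(c("has_imaging", "has_ist") %in% names(cohort)))
  cohort[cohort$has_imaging & cohort$has_ist, , drop = FALSE]
}

#' Write / read the cohort CSV interchange format
#'
#' Column names and units are those documented in [generateCohort()].
#'
#' @param cohort cohort table.
#' @param path CSV path.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(out))
    out$sex <- factor(out$sex, levels = c("female", "male"))
  out
}
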