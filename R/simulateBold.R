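#' Simulate per-ROI BOLD voxel time series for one subject
#'
#' Factor model of resting-state structure: each hippocampus has one latent
#' unit-variance white-noise factor `s(t)` (left/right factors correlated at
#' `hemisphereCor`); every hippocampal voxel follows
#' `x_v(t) = sqrt(rho_w) s(t) + sqrt(1 - rho_w) e_v(t)`, so within-ROI voxel
#' pairs are equicorrelated at `rho_w`. Each network's generator `g(t)` is
#' built to correlate with the left and right hippocampal factors at the
#' subject's coupling values, and network voxels load on `g(t)` at
#' `sqrt(rhoRsn)`. The cluster-level `rho_w` (per hemisphere) and `rho_c`
#' (per hemisphere x network) are jittered per subject on the logit scale
#' (`rhoLogitSd`) to create between-subject heterogeneity.
#'
#' The per-subject seed is a deterministic hash of `(config seed,
#' subject_id)`, so generation is order-independent and reproducible.
#'
#' @param subject one-row data.frame (or list) with `subject_id` and
#'   `latent_cluster`.
#' @param masks a [ROIMaskSet-class].
#' @param grid a [GridSpec-class].
#' @param config a [CohortConfig-class].
#' @return named list of V x T matrices, one per ROI (segments are the
#'   corresponding row subsets of their hippocampus), with the drawn
#'   subject-level rho values in `attr(, "rho")`.
#' @export
simulateRoiSeries <- function(subject, masks, grid, config) {
  if (is.null(subject$latent_cluster) || is.na(subject$latent_cluster))
    stop("simulation error: subject ", subject$subject_id,
         " has no latent cluster (real subjects cannot be simulated)")
  cl <- as.integer(subject$latent_cluster)
  seed <- subSeed(config@seed, subject$subject_id)
  withSeed(seed, {
    tn <- grid@nTimepoints
    h <- config@hemisphereCor
    jit <- function(rho) plogis(qlogis(rho) + rnorm(1, 0, config@rhoLogitSd))
    rhoW <- c(L = jit(config@rhoWithin[cl]), R = jit(config@rhoWithin[cl]))
    nets <- c("CEN", "SAL", "VIS", "SMN")
    rhoC <- matrix(vapply(seq_len(8), function(i) jit(config@rhoCross[cl]),
                          0),
                   2, 4, dimnames = list(c("L", "R"), nets))
    # keep the factor loadings of the network generators valid
    rhoC <- pmin(rhoC, 0.99 * sqrt((1 + h) / 2))

    u0 <- rnorm(tn)
    sL <- sqrt(h) * u0 + sqrt(1 - h) * rnorm(tn)
    sR <- sqrt(h) * u0 + sqrt(1 - h) * rnorm(tn)

    hippSeries <- function(s, v, rho)
      sqrt(rho) * matrix(s, v, tn, byrow = TRUE) +
        sqrt(1 - rho) * matrix(rnorm(v * tn), v, tn)

    out <- vector("list", length(roiNamesCanonical))
    names(out) <- roiNamesCanonical
    for (side in c("L", "R")) {
      hipp <- getMask(masks, paste0(side, "_hipp"))
      X <- hippSeries(if (side == "L") sL else sR,
                      sum(hipp@data), rhoW[[side]])
      out[[paste0(side, "_hipp")]] <- X
      for (seg in c("DG", "CA1sub")) {
        sm <- getMask(masks, paste0(side, "_", seg))
        out[[paste0(side, "_", seg)]] <- X[segmentRowsIn(sm, hipp), ,
                                           drop = FALSE]
      }
    }
    for (n in nets) {
      # solve the factor loadings so corr(g, sL) = rhoC["L", n] and
      # corr(g, sR) = rhoC["R", n] given corr(sL, sR) = h
      rl <- rhoC["L", n]; rr <- rhoC["R", n]
      wl <- (rl - h * rr) / (1 - h^2)
      wr <- (rr - h * rl) / (1 - h^2)
      fvar <- wl^2 + wr^2 + 2 * h * wl * wr
      if (fvar > 0.999) {  # guard against extreme jitter draws
        sc <- sqrt(0.999 / fvar)
        wl <- wl * sc; wr <- wr * sc; fvar <- 0.999
      }
      g <- wl * sL + wr * sR + sqrt(1 - fvar) * rnorm(tn)
      out[[n]] <- hippSeries(g, sum(getMask(masks, n)@data), config@rhoRsn)
    }
    attr(out, "rho") <- list(within = rhoW, cross = rhoC)
    out
  })
}

#' Embed a subject's simulated ROI series into a full 4D volume
#'
#' Calls [simulateRoiSeries()] and writes each ROI's voxel series into its
#' mask position (canonical lexicographic voxel order); all non-ROI voxels
#' are independent unit white noise. Extracting any ROI from the returned
#' volume with [extractRoiTimeseries()] therefore reproduces the ROI series
#' exactly.
#'
#' @inheritParams simulateRoiSeries
#' @return 4D array of dimension `c(grid dims, nTimepoints)`.
#' @export
simulateBoldVolume <- function(subject, masks, grid, config) {
  series <- simulateRoiSeries(subject, masks, grid, config)
  d <- grid@dims
  tn <- grid@nTimepoints
  flat <- matrix(0, prod(d), tn)
  roiIdx <- integer(0)
  for (nm in c("L_hipp", "R_hipp", "CEN", "SAL", "VIS", "SMN")) {
    idx <- which(getMask(masks, nm)@data)
    flat[idx, ] <- series[[nm]]
    roiIdx <- c(roiIdx, idx)
  }
  bg <- setdiff(seq_len(prod(d)), roiIdx)
  seed <- subSeed(config@seed, paste0(subject$subject_id, ":background"))
  withSeed(seed, flat[bg, ] <- rnorm(length(bg) * tn))
  array(flat, c(d, tn))
}

#' Expected voxel-to-rest correlation in the equicorrelated factor model
#'
#' For V equicorrelated voxels at correlation rho, the Pearson correlation
#' of one voxel with the mean of the other V - 1 voxels is
#' `rho * sqrt((V - 1) / (1 + (V - 2) rho))` — the population value of the
#' per-voxel cohesiveness correlation.
#'
#' @param rho within-ROI voxel correlation.
#' @param v number of voxels.
#' @export
expectedCohesivenessR <- function(rho, v)
  rho * sqrt((v - 1) / (1 + (v - 2) * rho))

#' Attenuation of a factor correlation after averaging V voxels
#'
#' Averaging V voxels that load on a factor at correlation `sqrt(rho)`
#' attenuates any correlation with that factor by
#' `sqrt(V rho / (1 + (V - 1) rho))`.
#'
#' @inheritParams expectedCohesivenessR
#' @export
averagingAttenuation <- function(rho, v)
  sqrt(v * rho / (1 + (v - 1) * rho))

#' @importFrom stats plogis qlogis
NULL
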