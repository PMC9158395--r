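#' Fisher Z transform with finite clipping
#'
#' `z = atanh(r)` after clipping `|r|` at `1 - 1e-7`, so perfectly
#' correlated inputs map to a large finite value (~8.41) instead of
#' infinity. Odd and strictly increasing on (-1, 1).
#'
#' @param r correlation value(s) in `[-1, 1]` (tolerance 1e-12).
#' @return Fisher-Z value(s).
#' @examples
#' fisherZ(0.5)       # 0.5493
#' fisherZ(1)         # finite, atanh(1 - 1e-7)
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("domain error: |r| > 1 in fisherZ")
  eps <- 1e-7
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Within-ROI functional cohesiveness
#'
#' For each voxel, the Pearson correlation of its series with the mean
#' series of all the other voxels is computed; cohesiveness is the mean of
#' the Fisher-Z transformed per-voxel correlations (`method = "loo"`, the
#' default leave-one-out reading). `method = "pairwise"` instead averages
#' the Fisher-Z transforms of all pairwise voxel correlations.
#'
#' Invariant to voxel order and to adding a constant or positive scale to
#' every series.
#'
#' @param x V x T voxel time-series matrix, V >= 2.
#' @param method `"loo"` (each voxel vs mean of the others) or
#'   `"pairwise"` (mean over voxel pairs).
#' @return scalar cohesiveness in Fisher-Z units.
#' @seealso [expectedCohesivenessR()] for the population value under the
#'   equicorrelated factor model.
#' @export
cohesiveness <- function(x, method = c("loo", "pairwise")) {
  method <- match.arg(method)
  if (is.null(dim(x)) || nrow(x) < 2L)
    stop("degenerate ROI: cohesiveness needs at least 2 voxels")
  if (method == "pairwise") {
    C <- cor(t(x))
    return(mean(fisherZ(C[upper.tri(C)])))
  }
  v <- nrow(x)
  cx <- x - rowMeans(x)
  s <- colSums(x)
  cs <- s - mean(s)
  a <- as.vector(cx %*% cs)       # sum_t cx[v,t] * cs[t]
  q <- rowSums(cx^2)
  s2 <- sum(cs^2)
  denom <- q * (s2 - 2 * a + q)
  if (any(denom <= 0))
    stop("degenerate ROI: zero-variance voxel or mean series")
  r <- (a - q) / sqrt(denom)
  mean(fisherZ(r))
}

#' Segment-to-network integration
#'
#' Fisher-Z transformed Pearson correlation between the mean series of a
#' hippocampal segment and the mean series of a resting-state network.
#'
#' @param segTs,rsnTs voxel time-series matrices with a common T.
#' @return scalar in Fisher-Z units.
#' @export
integrationZ <- function(segTs, rsnTs) {
  if (ncol(segTs) != ncol(rsnTs))
    stop("shape error: segment and network series differ in length")
  fisherZ(cor(meanTimeseries(segTs), meanTimeseries(rsnTs)))
}

#' Canonical names of the 7 metabolic clustering features
#'
#' @export
metabolicVars <- function() metabolicVarsCanonical

#' Canonical order of the 18 connectivity features
#'
#' Cohesiveness of the left and right hippocampus, then integration values
#' looping hemisphere (L, R) over segment (post = DG, ant = CA1/subiculum)
#' over network (CEN, SAL, VIS, SMN).
#'
#' @export
connectivityFeatureNames <- function() {
  nets <- c("CEN", "SAL", "VIS", "SMN")
  c("coh_L", "coh_R",
    as.vector(t(outer(
      as.vector(t(outer(c("L", "R"), c("post", "ant"), paste, sep = "_"))),
      nets, paste, sep = "_"))))
}

#' Per-subject 18-feature connectivity profile
#'
#' Computes the two cohesiveness values (whole hippocampi) and the sixteen
#' segment-to-network integration values, all in Fisher-Z units, in the
#' order of [connectivityFeatureNames()]. DG masks feed the posterior
#' integration values, CA1/subiculum masks the anterior ones.
#'
#' @param volume 4D BOLD array (ignored when `series` is given).
#' @param masks a [ROIMaskSet-class].
#' @param series optional pre-extracted named list of ROI matrices, as
#'   returned by [simulateRoiSeries()]; skips the extraction step.
#' @param method cohesiveness aggregation, see [cohesiveness()].
#' @return named numeric vector of 18 finite values.
#' @export
connectivityProfile <- function(volume = NULL, masks, series = NULL,
                                method = "loo") {
  if (is.null(series)) {
    if (is.null(volume)) stop("need either a volume or extracted series")
    series <- lapply(roiNamesCanonical, function(nm)
      extractRoiTimeseries(volume, getMask(masks, nm)))
    names(series) <- roiNamesCanonical
  }
  segOf <- c(post = "DG", ant = "CA1sub")
  out <- c(coh_L = cohesiveness(series$L_hipp, method),
           coh_R = cohesiveness(series$R_hipp, method))
  for (side in c("L", "R"))
    for (seg in c("post", "ant"))
      for (net in c("CEN", "SAL", "VIS", "SMN"))
        out[paste(side, seg, net, sep = "_")] <-
          integrationZ(series[[paste0(side, "_", segOf[[seg]])]],
                       series[[net]])
  out <- out[connectivityFeatureNames()]
  if (any(!is.finite(out)))
    stop("non-finite connectivity feature: ",
         paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}

#' Connectivity profiles for every complete subject of a synthetic cohort
#'
#' Simulates each complete subject's ROI series (deterministically seeded
#' per subject) and assembles the cohort-level subjects x 18 feature table.
#'
#' @param cohort cohort table from [generateCohort()].
#' @param masks,grid,config simulation inputs; see [simulateRoiSeries()].
#' @param method cohesiveness aggregation.
#' @return data.frame: `subject_id` plus the 18 named features.
#' @export
cohortConnectivity <- function(cohort, masks, grid, config, method = "loo") {
  complete <- filterComplete(cohort)
  profs <- t(vapply(seq_len(nrow(complete)), function(i) {
    series <- simulateRoiSeries(complete[i, ], masks, grid, config)
    connectivityProfile(masks = masks, series = series, method = method)
  }, numeric(18)))
  data.frame(subject_id = complete$subject_id, profs,
             stringsAsFactors = FALSE)
}
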