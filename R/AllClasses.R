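#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor dnorm pnorm qnorm rnorm runif rbinom rlnorm sd var
#'   uniroot dist p.adjust shapiro.test t.test wilcox.test chisq.test
#'   fisher.test lm.fit pt complete.cases quantile
#' @importFrom utils head read.csv write.csv
NULL

roiNamesCanonical <- c("L_hipp", "R_hipp", "L_DG", "R_DG",
                       "L_CA1sub", "R_CA1sub", "CEN", "SAL", "VIS", "SMN")

metabolicVarsCanonical <- c("BMI", "WC", "SSPG", "FPI", "FPG",
                            "leptin", "cortisol")

#' Configuration of the synthetic cohort generator
#'
#' Holds the study-design constants of the simulated cohort: enrollment and
#' completeness counts, the two planted cluster sizes, per-cluster means and
#' SDs of the seven metabolic variables, their correlation matrix, the
#' demographic/cognitive/motion marginals (cluster-invariant), and the
#' per-cluster BOLD factor-model effect sizes (`rhoWithin`, `rhoCross`).
#'
#' Cluster 1 is, by convention, the higher metabolic-deviance cluster.
#'
#' @slot nEnrolled,nComplete enrolled subjects and subjects with both
#'   neuroimaging and insulin-suppression-test data.
#' @slot clusterSizes sizes of the two planted clusters among complete
#'   subjects; must sum to `nComplete`.
#' @slot metabolicVars,clusterMeans,clusterSds metabolic variable names and
#'   the 2 x 7 matrices of per-cluster marginal means/SDs (rows = clusters).
#' @slot metabolicCor 7 x 7 positive semi-definite correlation matrix of the
#'   metabolic block.
#' @slot femaleFraction per-cluster probability that a subject is female.
#' @slot ageMean,ageSd,ethnicityLevels,ethnicityProbs,iqMean,iqSd,memoryMeans,memorySds
#'   cluster-invariant demographic and cognitive marginals.
#' @slot motionMeanlog,motionSdlog,motionMaxExcessMeanlog,motionMaxExcessSdlog
#'   lognormal parameters for mean volume-to-volume head displacement (mm) and
#'   for the positive excess of the maximum over the mean.
#' @slot rhoWithin,rhoCross per-cluster within-hippocampus voxel correlation
#'   and segment-factor-to-network coupling of the BOLD factor model.
#' @slot rhoRsn within-network voxel correlation (cluster-invariant).
#' @slot hemisphereCor correlation between the left and right hippocampal
#'   latent factors.
#' @slot rhoLogitSd SD of the per-subject jitter applied to `rhoWithin` and
#'   `rhoCross` on the logit scale (between-subject heterogeneity).
#' @slot seed master seed; every stochastic stage derives its own stream
#'   from it.
#' @export
setClass("CohortConfig", representation(
  nEnrolled = "integer", nComplete = "integer", clusterSizes = "integer",
  metabolicVars = "character", clusterMeans = "matrix", clusterSds = "matrix",
  metabolicCor = "matrix", femaleFraction = "numeric",
  ageMean = "numeric", ageSd = "numeric",
  ethnicityLevels = "character", ethnicityProbs = "numeric",
  iqMean = "numeric", iqSd = "numeric",
  memoryMeans = "numeric", memorySds = "numeric",
  motionMeanlog = "numeric", motionSdlog = "numeric",
  motionMaxExcessMeanlog = "numeric", motionMaxExcessSdlog = "numeric",
  rhoWithin = "numeric", rhoCross = "numeric", rhoRsn = "numeric",
  hemisphereCor = "numeric", rhoLogitSd = "numeric",
  seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (length(object@clusterSizes) != 2L ||
      sum(object@clusterSizes) != object@nComplete)
    msg <- c(msg, "cluster sizes must be two counts summing to nComplete")
  if (object@nComplete > object@nEnrolled)
    msg <- c(msg, "nComplete cannot exceed nEnrolled")
  p <- length(object@metabolicVars)
  if (!all(dim(object@clusterMeans) == c(2L, p)) ||
      !all(dim(object@clusterSds) == c(2L, p)))
    msg <- c(msg, "clusterMeans/clusterSds must be 2 x length(metabolicVars)")
  if (any(object@clusterSds <= 0))
    msg <- c(msg, "all metabolic SDs must be > 0")
  R <- object@metabolicCor
  if (!all(dim(R) == c(p, p)) || any(abs(R - t(R)) > 1e-8) ||
      any(abs(diag(R) - 1) > 1e-8))
    msg <- c(msg, "metabolic correlation matrix must be symmetric with unit diagonal")
  else if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "metabolic correlation matrix is not positive semi-definite")
  if (any(object@femaleFraction < 0 | object@femaleFraction > 1))
    msg <- c(msg, "femaleFraction must lie in [0, 1]")
  rho <- c(object@rhoWithin, object@rhoCross, object@rhoRsn)
  if (any(rho < 0 | rho >= 1))
    msg <- c(msg, "all rho parameters must lie in [0, 1)")
  if (object@hemisphereCor < 0 || object@hemisphereCor >= 1)
    msg <- c(msg, "hemisphereCor must lie in [0, 1)")
  if (any(object@rhoCross > sqrt((1 + object@hemisphereCor) / 2)))
    msg <- c(msg, "rhoCross must not exceed sqrt((1 + hemisphereCor)/2)")
  if (length(msg)) msg else TRUE
})

#' Voxel grid of the simulated acquisitions
#'
#' @slot dims x/y/z voxel counts.
#' @slot voxelMm isotropic voxel size in mm (metadata only).
#' @slot nTimepoints,tr number of BOLD volumes and repetition time (s).
#' @export
setClass("GridSpec", representation(
  dims = "integer", voxelMm = "numeric", nTimepoints = "integer",
  tr = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive voxel counts")
  if (object@nTimepoints < 10L)
    return("need at least 10 timepoints")
  TRUE
})

#' A named region-of-interest mask on a voxel grid
#'
#' @slot name ROI name (one of the ten canonical ROIs for pipeline use).
#' @slot data logical 3D array, TRUE inside the ROI.
#' @export
setClass("ROIMask", representation(name = "character", data = "array"))

setValidity("ROIMask", function(object) {
  if (length(dim(object@data)) != 3L) return("mask must be a 3D array")
  if (!is.logical(object@data)) return("mask array must be logical")
  if (!any(object@data)) return("mask has no voxels")
  TRUE
})

#' The ten-ROI mask set used by the connectivity stage
#'
#' Left/right whole hippocampus, the posterior (DG) and anterior
#' (CA1/subiculum) segments nested inside each hippocampus, and the four
#' resting-state networks (CEN, SAL, VIS, SMN), all on one voxel lattice.
#'
#' @slot masks named list of [ROIMask-class] objects.
#' @slot dims shared grid dimensions.
#' @export
setClass("ROIMaskSet", representation(masks = "list", dims = "integer"))

setValidity("ROIMaskSet", function(object) {
  if (!identical(sort(names(object@masks)), sort(roiNamesCanonical)))
    return(paste("mask set must contain exactly:",
                 paste(roiNamesCanonical, collapse = ", ")))
  ok <- vapply(object@masks, function(m)
    identical(dim(m@data), as.integer(object@dims)), logical(1))
  if (!all(ok)) return("all masks must share the grid dimensions")
  TRUE
})

#' Standardized subjects-by-features container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with features as rows (7 metabolic + 18 connectivity) and subjects as
#' columns. Assay `"raw"` holds the measured values, assay `"scaled"` the
#' column z-scores; `rowData` records each feature's block
#' (metabolic/connectivity) and the standardization center/scale so the
#' transform is invertible.
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  if (!all(c("raw", "scaled") %in% SummarizedExperiment::assayNames(object)))
    return("FeatureMatrix needs 'raw' and 'scaled' assays")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("block", "center", "scale") %in% colnames(rd)))
    return("rowData must record block, center and scale")
  if (any(!is.finite(SummarizedExperiment::assay(object, "scaled"))))
    return("scaled assay contains non-finite values")
  TRUE
})

#' Result of majority-vote k selection and final k-means fit
#'
#' @slot kRange candidate numbers of clusters.
#' @slot criteria indices x k matrix of criterion values (NA = abstained).
#' @slot orientation per-index rule used to turn criteria into a vote.
#' @slot votes named integer vector: each index's nominated k (NA = abstain).
#' @slot tally votes per candidate k.
#' @slot chosenK plurality winner (ties broken toward smaller k).
#' @slot labels final cluster labels, deviance-ordered (cluster 1 = highest
#'   metabolic deviance) once [orderByDeviance()] has been applied.
#' @slot centroids cluster centroids in standardized feature space.
#' @slot withinSS total within-cluster sum of squares at `chosenK`.
#' @slot wssByK total within-cluster SS for each fitted k (including the
#'   flanking k used by elbow-type indices).
#' @slot devianceOrdered whether labels have been canonicalized.
#' @export
setClass("ClusterSolution", representation(
  kRange = "integer", criteria = "matrix", orientation = "character",
  votes = "integer", tally = "integer", chosenK = "integer",
  labels = "integer", centroids = "matrix", withinSS = "numeric",
  wssByK = "numeric", devianceOrdered = "logical"))

setValidity("ClusterSolution", function(object) {
  if (!(object@chosenK %in% object@kRange))
    return("chosenK must lie in the candidate range")
  if (length(object@labels) &&
      !all(object@labels %in% seq_len(object@chosenK)))
    return("labels must lie in 1..chosenK")
  TRUE
})

#' Covariate-adjusted Spearman association matrix
#'
#' @slot rho,p symmetric matrices of Spearman rho and two-sided p-values.
#' @slot adjusted whether variables were residualized on age and sex first.
#' @export
setClass("AssociationMatrix", representation(
  rho = "matrix", p = "matrix", adjusted = "logical"))

setValidity("AssociationMatrix", function(object) {
  if (!identical(dim(object@rho), dim(object@p)))
    return("rho and p must have identical dimensions")
  if (any(abs(object@rho) > 1 + 1e-12, na.rm = TRUE))
    return("|rho| must not exceed 1")
  if (any(abs(object@rho - t(object@rho)) > 1e-8, na.rm = TRUE))
    return("rho matrix must be symmetric")
  TRUE
})
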