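#' Column z-scores with stored parameters
#'
#' @param m subjects x features numeric matrix.
#' @return list with `scaled`, `center`, `scale` (sample SD). A zero-SD
#'   column is an error naming the column.
#' @export
standardizeFeatures <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 subjects to standardize")
  if (any(!is.finite(m))) stop("non-finite values in feature matrix")
  center <- colMeans(m)
  scale <- apply(m, 2, sd)
  if (any(scale == 0))
    stop("zero-variance feature column(s): ",
         paste(colnames(m)[scale == 0], collapse = ", "))
  list(scaled = sweep(sweep(m, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Assemble the 25-feature matrix for clustering
#'
#' Joins the metabolic panel (7 variables) of the complete cohort with the
#' 18 connectivity features by `subject_id` and standardizes each feature
#' (sample-SD z-scores). The result is a [FeatureMatrix-class]
#' (SummarizedExperiment; features as rows, subjects as columns) whose
#' `colData` keeps the demographic/cognitive/motion columns and, for
#' synthetic cohorts, the planted `latent_cluster`.
#'
#' @param cohort cohort table (will be filtered to complete cases).
#' @param connectivity subjects x 18 table from [cohortConnectivity()],
#'   with a `subject_id` column.
#' @return a [FeatureMatrix-class] with 25 feature rows.
#' @export
buildFeatureMatrix <- function(cohort, connectivity) {
  complete <- filterComplete(cohort)
  m <- merge(complete, connectivity, by = "subject_id", sort = FALSE)
  if (nrow(m) != nrow(complete) || nrow(m) != nrow(connectivity))
    stop("join error: cohort and connectivity tables do not align")
  featNames <- c(metabolicVarsCanonical, connectivityFeatureNames())
  missing <- setdiff(featNames, names(m))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  raw <- as.matrix(m[, featNames])
  if (anyNA(raw)) stop("missing values among clustering features")
  std <- standardizeFeatures(raw)
  block <- c(rep("metabolic", length(metabolicVarsCanonical)),
             rep("connectivity", length(connectivityFeatureNames())))
  keep <- setdiff(names(m), featNames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(raw = t(raw), scaled = t(std$scaled)),
    rowData = S4Vectors::DataFrame(block = block, center = std$center,
                                   scale = std$scale,
                                   row.names = featNames),
    colData = S4Vectors::DataFrame(m[, keep], row.names = m$subject_id))
  new("FeatureMatrix", se)
}

#' Subjects-by-features view of the standardized values
#'
#' @param fm a [FeatureMatrix-class].
#' @param block optionally restrict to `"metabolic"` or `"connectivity"`
#'   features.
#' @return subjects x features numeric matrix of z-scores.
#' @export
scaledFeatures <- function(fm, block = NULL) {
  m <- t(SummarizedExperiment::assay(fm, "scaled"))
  if (!is.null(block)) {
    keep <- SummarizedExperiment::rowData(fm)$block == block
    m <- m[, keep, drop = FALSE]
  }
  m
}

#' @rdname scaledFeatures
#' @export
rawFeatures <- function(fm, block = NULL) {
  m <- t(SummarizedExperiment::assay(fm, "raw"))
  if (!is.null(block)) {
    keep <- SummarizedExperiment::rowData(fm)$block == block
    m <- m[, keep, drop = FALSE]
  }
  m
}
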