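#' Select the number of clusters by majority vote
#'
#' Runs [computeCriteria()] over the candidate range, lets every
#' non-abstaining validity index nominate its optimal k, and chooses the
#' plurality winner (ties broken toward the smaller k, favouring
#' parsimony). At least three indices must cast a vote.
#'
#' @param features a [FeatureMatrix-class] or a subjects x features
#'   (already standardized) matrix.
#' @param kRange candidate cluster numbers.
#' @param seed RNG seed governing all fits and gap references.
#' @param nInit k-means++ restarts per fit.
#' @param gapRefs gap-statistic reference draws.
#' @param block optional feature-block restriction (`"metabolic"`), see
#'   [scaledFeatures()].
#' @return a [ClusterSolution-class]; labels are not yet deviance-ordered
#'   (see [orderByDeviance()]).
#' @export
selectKMajority <- function(features, kRange = 2:8, seed = 1, nInit = 50,
                            gapRefs = 50, block = NULL) {
  x <- if (is(features, "FeatureMatrix")) scaledFeatures(features, block)
       else as.matrix(features)
  cr <- computeCriteria(x, kRange = kRange, seed = seed, nInit = nInit,
                        gapRefs = gapRefs)
  votes <- cr$votes
  if (sum(!is.na(votes)) < 3L)
    stop("selection error: fewer than 3 validity indices cast a vote")
  kRange <- sort(as.integer(kRange))
  tally <- vapply(kRange, function(k) sum(votes == k, na.rm = TRUE),
                  integer(1))
  names(tally) <- kRange
  chosen <- kRange[which.max(tally)]  # which.max takes the smallest on ties
  fit <- cr$fits[[as.character(chosen)]]
  new("ClusterSolution",
      kRange = kRange, criteria = cr$criteria,
      orientation = indexOrientations[validityIndexNames],
      votes = votes, tally = tally, chosenK = as.integer(chosen),
      labels = as.integer(fit$labels), centroids = fit$centers,
      withinSS = fit$wss, wssByK = cr$wss, devianceOrdered = FALSE)
}

#' Canonicalize cluster labels by metabolic deviance
#'
#' Scores each cluster by the mean of its subjects' standardized SSPG and
#' leptin values and relabels clusters in decreasing deviance order, so
#' cluster 1 is always the metabolically most deviant one. An exact tie is
#' resolved by decreasing cluster size (with a message).
#'
#' @param solution a [ClusterSolution-class].
#' @param features the [FeatureMatrix-class] the solution was fitted on
#'   (used for the standardized SSPG/leptin columns).
#' @return the relabeled [ClusterSolution-class].
#' @export
orderByDeviance <- function(solution, features) {
  z <- scaledFeatures(features)[, c("SSPG", "leptin"), drop = FALSE]
  if (nrow(z) != length(solution@labels))
    stop("join error: feature matrix and labels do not align")
  k <- solution@chosenK
  score <- vapply(seq_len(k), function(j)
    mean(z[solution@labels == j, , drop = FALSE]), 0)
  sizes <- tabulate(solution@labels, k)
  if (anyDuplicated(score)) {
    message("deviance tie: ordering tied clusters by size")
    ord <- order(-score, -sizes)
  } else ord <- order(-score)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  solution@labels <- relabel[solution@labels]
  solution@centroids <- solution@centroids[ord, , drop = FALSE]
  solution@devianceOrdered <- TRUE
  validObject(solution)
  solution
}

#' Metabolic-only clustering variant
#'
#' The supplementary-style analysis: identical majority-vote procedure
#' restricted to the 7 blood-based metabolic features.
#'
#' @inheritParams selectKMajority
#' @param order apply [orderByDeviance()] to the result?
#' @return a [ClusterSolution-class].
#' @export
clusterMetabolicOnly <- function(features, kRange = 2:8, seed = 1,
                                 nInit = 50, gapRefs = 50, order = TRUE) {
  sol <- selectKMajority(features, kRange = kRange, seed = seed,
                         nInit = nInit, gapRefs = gapRefs,
                         block = "metabolic")
  if (order && is(features, "FeatureMatrix"))
    sol <- orderByDeviance(sol, features)
  sol
}
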