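#' @rdname ClusterSolution-class
#' @param object,x a package object
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("voteTally", function(object) standardGeneric("voteTally"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("indexVotes", function(object) standardGeneric("indexVotes"))

#' @rdname ClusterSolution-class
#' @export
setGeneric("criteriaValues", function(object) standardGeneric("criteriaValues"))

#' @rdname AssociationMatrix-class
#' @export
setGeneric("rhoValues", function(object) standardGeneric("rhoValues"))

#' @rdname AssociationMatrix-class
#' @export
setGeneric("pValues", function(object) standardGeneric("pValues"))

#' @rdname ROIMaskSet-class
#' @param name ROI name
#' @export
setGeneric("getMask", function(object, name) standardGeneric("getMask"))

#' @rdname ROIMaskSet-class
#' @export
setGeneric("maskSizes", function(object) standardGeneric("maskSizes"))

setMethod("chosenK", "ClusterSolution", function(object) object@chosenK)
setMethod("clusterLabels", "ClusterSolution", function(object) object@labels)
setMethod("voteTally", "ClusterSolution", function(object) object@tally)
setMethod("indexVotes", "ClusterSolution", function(object) object@votes)
setMethod("criteriaValues", "ClusterSolution", function(object) object@criteria)
setMethod("rhoValues", "AssociationMatrix", function(object) object@rho)
setMethod("pValues", "AssociationMatrix", function(object) object@p)
setMethod("getMask", "ROIMaskSet", function(object, name) {
  if (!name %in% names(object@masks))
    stop("unknown ROI: ", name)
  object@masks[[name]]
})
setMethod("maskSizes", "ROIMaskSet", function(object)
  vapply(object@masks, function(m) sum(m@data), integer(1)))

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nEnrolled, "enrolled,",
      object@nComplete, "complete; planted clusters",
      paste(object@clusterSizes, collapse = "/"), "\n")
  cat("  metabolic:", paste(object@metabolicVars, collapse = ", "), "\n")
  cat("  rho_within:", paste(object@rhoWithin, collapse = "/"),
      " rho_cross:", paste(object@rhoCross, collapse = "/"),
      " seed:", object@seed, "\n")
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", paste(object@dims, collapse = " x "), "voxels,",
      object@nTimepoints, "timepoints, TR", object@tr, "s\n")
})

setMethod("show", "ROIMaskSet", function(object) {
  s <- maskSizes(object)
  cat("ROIMaskSet on", paste(object@dims, collapse = " x "), "grid:\n")
  for (n in roiNamesCanonical) cat(sprintf("  %-9s %d voxels\n", n, s[[n]]))
})

setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution: chosen k =", object@chosenK,
      if (object@devianceOrdered) "(deviance-ordered labels)" else "", "\n")
  cat("  vote tally:", paste(sprintf("k=%s:%d", names(object@tally),
                                     object@tally), collapse = " "), "\n")
  if (length(object@labels))
    cat("  cluster sizes:",
        paste(tabulate(object@labels, object@chosenK), collapse = "/"), "\n")
})

setMethod("show", "AssociationMatrix", function(object) {
  cat("AssociationMatrix over", nrow(object@rho), "variables",
      if (object@adjusted) "(age/sex-adjusted)" else "(unadjusted)", "\n")
})
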