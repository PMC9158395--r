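#' Build a synthetic-cohort configuration
#'
#' Constructs a [CohortConfig-class] from a nested list with the same layout
#' as the shipped `table2_defaults.yaml` (see [defaultCohortConfig()]).
#' Individual fields can be overridden through `...` using the slot names,
#' e.g. `cohortConfig(seed = 7, rhoWithin = c(0.2, 0.2))`.
#'
#' @param spec nested list parsed from the YAML schema; defaults to the
#'   shipped configuration.
#' @param ... slot-level overrides applied after parsing.
#' @return a validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' cfg
#' @export
cohortConfig <- function(spec = NULL, ...) {
  if (is.null(spec))
    spec <- yaml::read_yaml(system.file("extdata", "table2_defaults.yaml",
                                        package = "hippoclust"))
  mv <- as.character(spec$metabolic$variables)
  toMat <- function(m1, m2) {
    m <- rbind(cluster1 = as.numeric(m1), cluster2 = as.numeric(m2))
    colnames(m) <- mv
    m
  }
  R <- do.call(rbind, lapply(spec$metabolic$correlation, as.numeric))
  dimnames(R) <- list(mv, mv)
  if (any(abs(R - t(R)) > 1e-8) ||
      min(eigen((R + t(R)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("configuration error: metabolic correlation matrix is not a valid ",
         "(symmetric positive semi-definite) correlation matrix")
  obj <- new("CohortConfig",
    nEnrolled = as.integer(spec$n_enrolled),
    nComplete = as.integer(spec$n_complete),
    clusterSizes = as.integer(spec$cluster_sizes),
    metabolicVars = mv,
    clusterMeans = toMat(spec$metabolic$cluster1$mean,
                         spec$metabolic$cluster2$mean),
    clusterSds = toMat(spec$metabolic$cluster1$sd,
                       spec$metabolic$cluster2$sd),
    metabolicCor = R,
    femaleFraction = as.numeric(spec$female_fraction),
    ageMean = as.numeric(spec$age$mean), ageSd = as.numeric(spec$age$sd),
    ethnicityLevels = as.character(spec$ethnicity$levels),
    ethnicityProbs = as.numeric(spec$ethnicity$probs),
    iqMean = as.numeric(spec$cognitive$iq$mean),
    iqSd = as.numeric(spec$cognitive$iq$sd),
    memoryMeans = c(pairing = as.numeric(spec$cognitive$memory_pairing$mean),
                    recall = as.numeric(spec$cognitive$memory_recall$mean)),
    memorySds = c(pairing = as.numeric(spec$cognitive$memory_pairing$sd),
                  recall = as.numeric(spec$cognitive$memory_recall$sd)),
    motionMeanlog = as.numeric(spec$motion$meanlog),
    motionSdlog = as.numeric(spec$motion$sdlog),
    motionMaxExcessMeanlog = as.numeric(spec$motion$max_excess_meanlog),
    motionMaxExcessSdlog = as.numeric(spec$motion$max_excess_sdlog),
    rhoWithin = as.numeric(spec$connectivity$rho_within),
    rhoCross = as.numeric(spec$connectivity$rho_cross),
    rhoRsn = as.numeric(spec$connectivity$rho_rsn),
    hemisphereCor = as.numeric(spec$connectivity$hemisphere_cor),
    rhoLogitSd = as.numeric(spec$connectivity$rho_logit_sd),
    seed = as.integer(spec$seed))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% slotNames(obj)) stop("unknown CohortConfig field: ", nm)
    value <- dots[[nm]]
    if (is(slot(obj, nm), "integer")) value <- as.integer(value)
    slot(obj, nm) <- value
  }
  validObject(obj)
  obj
}

#' The shipped default configuration
#'
#' Per-cluster SSPG and leptin means/SDs are the published cluster
#' statistics; BMI and FPG marginals reproduce the published FPG- and
#' BMI-category percentages of the complete sample; the remaining marginals
#' are realistic defaults. See `inst/extdata/table2_defaults.yaml`.
#'
#' @param ... overrides forwarded to [cohortConfig()].
#' @return a [CohortConfig-class].
#' @export
defaultCohortConfig <- function(...) cohortConfig(NULL, ...)

#' Read a cohort configuration from a YAML file
#'
#' @param path YAML file following the `table2_defaults.yaml` schema.
#' @param ... overrides forwarded to [cohortConfig()].
#' @export
readCohortConfig <- function(path, ...) cohortConfig(yaml::read_yaml(path), ...)
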