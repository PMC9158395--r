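#' Run the full synthetic analysis pipeline
#'
#' One reproducible end-to-end run: generate the cohort, filter to
#' complete cases, simulate per-subject ROI BOLD series, compute the
#' 18-feature connectivity profiles, assemble and standardize the
#' 25-feature matrix, (optionally) build the age/sex-adjusted association
#' matrix, select k by majority vote, canonicalize labels by metabolic
#' deviance, and (optionally) compare the clusters. Identical
#' `(config, seed)` give bitwise-identical results; every stochastic stage
#' derives its own stream from the master seed.
#'
#' @param seed master seed for the run (overrides `config@seed`).
#' @param config a [CohortConfig-class].
#' @param grid a [GridSpec-class].
#' @param mode `"full"` (25 features) or `"metabolic"` (7 blood-based
#'   features only, the supplementary-style variant).
#' @param kRange,nInit,gapRefs clustering controls, see
#'   [selectKMajority()].
#' @param associate,compare run the association-matrix / cluster-comparison
#'   stages?
#' @param outDir optional directory; when given, the cohort, feature and
#'   label tables, association matrices, comparison report, summary and run
#'   manifest are written there as CSV/JSON.
#' @param verbose log per-stage timings?
#' @return named list: `cohort`, `complete`, `masks`, `connectivity`,
#'   `features` ([FeatureMatrix-class]), `association`, `solution`
#'   ([ClusterSolution-class]), `report`, `summary`, `manifest`.
#' @examples
#' \donttest{
#' run <- runPipeline(seed = 42, grid = gridSpec(nTimepoints = 60),
#'                    gapRefs = 10, nInit = 10, verbose = FALSE)
#' run$summary$chosen_k
#' }
#' @export
runPipeline <- function(seed = 42, config = defaultCohortConfig(),
                        grid = defaultGridSpec(), mode = c("full", "metabolic"),
                        kRange = 2:8, nInit = 50, gapRefs = 50,
                        associate = TRUE, compare = TRUE, outDir = NULL,
                        verbose = TRUE) {
  mode <- match.arg(mode)
  config@seed <- as.integer(seed)
  validObject(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(nm) {
    t1 <- proc.time()[["elapsed"]]
    timings[[nm]] <<- round(t1 - t0, 3)
    if (verbose) message(sprintf("[%s] done at %.1fs", nm, t1 - t0))
    t0 <<- t1
  }

  cohort <- generateCohort(config)
  complete <- filterComplete(cohort)
  stage("simulate_cohort")

  masks <- generateMasks(grid)
  conn <- cohortConnectivity(cohort, masks, grid, config)
  stage("connectivity")

  features <- buildFeatureMatrix(cohort, conn)
  stage("features")

  association <- NULL
  if (associate) {
    tbl <- as.data.frame(rawFeatures(features))
    association <- associationMatrix(tbl, adjust = TRUE,
                                     age = complete$age,
                                     sex = complete$sex)
    stage("association")
  }

  sol <- selectKMajority(features, kRange = kRange,
                         seed = subSeed(seed, "cluster"), nInit = nInit,
                         gapRefs = gapRefs,
                         block = if (mode == "metabolic") "metabolic")
  sol <- orderByDeviance(sol, features)
  stage("clustering")

  report <- NULL
  if (compare) {
    report <- compareClusters(cohort, conn, clusterLabels(sol))
    stage("comparison")
  }

  lab <- clusterLabels(sol)
  raw <- rawFeatures(features)
  perCluster <- function(v) vapply(seq_len(chosenK(sol)), function(j)
    mean(raw[lab == j, v]), 0)
  summary <- list(
    mode = mode, seed = as.integer(seed),
    n_enrolled = nrow(cohort), n_complete = nrow(complete),
    chosen_k = chosenK(sol),
    cluster_sizes = as.integer(tabulate(lab, chosenK(sol))),
    sspg_by_cluster = perCluster("SSPG"),
    leptin_by_cluster = perCluster("leptin"),
    vote_tally = as.list(voteTally(sol)),
    ari_vs_latent = if (!is.null(complete$latent_cluster))
      adjustedRand(lab, complete$latent_cluster) else NA_real_,
    pct_fpg_normal = 100 * mean(classifyFpg(complete$FPG) == "normal"),
    pct_overweight = 100 * mean(classifyBmi(complete$BMI) == "overweight"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hippoclust")),
    seed = as.integer(seed), mode = mode,
    grid = list(dims = grid@dims, n_timepoints = grid@nTimepoints),
    stage_seconds = as.list(timings),
    fingerprints = list(cohort = fingerprintOf(cohort),
                        connectivity = fingerprintOf(conn),
                        labels = fingerprintOf(lab)))

  out <- list(cohort = cohort, complete = complete, masks = masks,
              connectivity = conn, features = features,
              association = association, solution = sol, report = report,
              summary = summary, manifest = manifest)
  if (!is.null(outDir)) writeRunBundle(out, outDir)
  out
}

#' Write a pipeline run to disk
#'
#' @param run result of [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunBundle <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeCohort(run$cohort, file.path(outDir, "cohort.csv"))
  write.csv(run$connectivity, file.path(outDir, "connectivity.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject_id = colnames(run$features),
                       cluster = clusterLabels(run$solution)),
            file.path(outDir, "labels.csv"), row.names = FALSE)
  write.csv(as.data.frame(criteriaValues(run$solution)),
            file.path(outDir, "criteria.csv"))
  if (!is.null(run$association)) {
    write.csv(rhoValues(run$association), file.path(outDir, "rho.csv"))
    write.csv(pValues(run$association), file.path(outDir, "p.csv"))
  }
  if (!is.null(run$report))
    write.csv(run$report, file.path(outDir, "comparison.csv"),
              row.names = FALSE)
  jsonlite::write_json(run$summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
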