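#' Normality gate for test selection
#'
#' Shapiro-Wilk at alpha = 0.05 on the pooled residuals from cluster means
#' decides whether a variable is compared with Welch's t (normal) or the
#' Mann-Whitney U test (nonnormal). Fewer than 8 observations, or a
#' degenerate (constant) variable, defaults to nonnormal with a warning.
#'
#' @param values numeric vector.
#' @param groups optional grouping; residuals are taken about group means.
#' @return `"normal"` or `"nonnormal"`.
#' @export
normalityGate <- function(values, groups = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 8L) {
    warning("fewer than 8 observations: defaulting to nonnormal")
    return("nonnormal")
  }
  if (var(values) == 0) {
    warning("constant variable: defaulting to nonnormal")
    return("nonnormal")
  }
  resid <- if (is.null(groups)) values - mean(values)
           else values - ave(values, groups)
  if (shapiro.test(resid)$p.value < 0.05) "nonnormal" else "normal"
}

#' Two-group and contingency tests used in cluster comparisons
#'
#' Thin, policy-carrying wrappers: `mannWhitney` uses mid-ranks with exact
#' enumeration when the smaller group has <= 8 observations (and no ties)
#' and the continuity-corrected normal approximation otherwise; `welchT` is
#' the unequal-variance t test; `chiSquare` applies Yates' correction for
#' 2 x 2 tables only and falls back to Fisher's exact test when any
#' expected count drops below 5.
#'
#' @param x,y numeric group vectors (>= 3 each).
#' @return list with `statistic`, `p` and the test `name`.
#' @export
mannWhitney <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("group sizes must be at least 3")
  if (var(c(x, y)) == 0) stop("undefined test: all observations tied")
  exact <- min(length(x), length(y)) <= 8L
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p = ht$p.value,
       name = "Mann-Whitney U")
}

#' @rdname mannWhitney
#' @export
welchT <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop("group sizes must be at least 3")
  if (var(c(x, y)) == 0) stop("undefined test: all observations tied")
  ht <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value, name = "Welch t")
}

#' @rdname mannWhitney
#' @param tab contingency table (groups x categories).
#' @export
chiSquare <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- fisher.test(tab)
    return(list(statistic = NA_real_, p = ht$p.value,
                name = "Fisher exact"))
  }
  ht <- suppressWarnings(chisq.test(tab))  # Yates for 2x2 only (default)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       name = "chi-square")
}

compareContinuous <- function(x, y, forceGate = NULL) {
  gate <- if (is.null(forceGate))
    normalityGate(c(x, y), rep(1:2, c(length(x), length(y))))
  else forceGate
  res <- if (gate == "normal") welchT(x, y) else mannWhitney(x, y)
  c(res, list(normal = gate))
}

#' Compare the two clusters across all study variables
#'
#' Builds a publication-style report: per continuous variable the
#' cluster-wise mean (SD), the test chosen by [normalityGate()] and its
#' p-value; per categorical variable the cluster-wise counts and a
#' chi-square (or Fisher exact) test. Covers the 7 metabolic variables,
#' age, IQ, the two memory subtests, mean/max head displacement, sex,
#' ethnicity, and the 18 connectivity features. No multiplicity correction
#' is applied by default (the report mirrors how such cluster tables are
#' presented); `adjust = TRUE` adds Benjamini-Hochberg adjusted p-values.
#'
#' @param cohort complete-case cohort table.
#' @param connectivity subjects x 18 connectivity table with `subject_id`
#'   (as from [cohortConnectivity()]), or NULL to skip the connectivity
#'   block.
#' @param labels integer cluster labels aligned with the cohort rows
#'   (cluster 1 = higher deviance after [orderByDeviance()]).
#' @param adjust add a BH-adjusted p-value column?
#' @return data.frame report, one row per compared variable.
#' @export
compareClusters <- function(cohort, connectivity = NULL, labels,
                            adjust = FALSE) {
  cohort <- filterComplete(cohort)
  if (nrow(cohort) != length(labels))
    stop("join error: labels and cohort rows do not align")
  if (!is.null(connectivity)) {
    m <- merge(cohort[, "subject_id", drop = FALSE], connectivity,
               by = "subject_id", sort = FALSE)
    if (nrow(m) != nrow(cohort))
      stop("join error: connectivity table does not cover the cohort")
    cohort <- cbind(cohort, m[match(cohort$subject_id, m$subject_id),
                              setdiff(names(m), "subject_id")])
  }
  contVars <- c("age", metabolicVarsCanonical, "IQ", "memory_pairing",
                "memory_recall", "motion_mean_mm", "motion_max_mm")
  if (!is.null(connectivity))
    contVars <- c(contVars, connectivityFeatureNames())
  catVars <- c("sex", "ethnicity")
  contVars <- intersect(contVars, names(cohort))
  catVars <- intersect(catVars, names(cohort))

  g1 <- labels == 1L
  rows <- list()
  for (v in contVars) {
    x <- cohort[[v]][g1]; y <- cohort[[v]][!g1]
    res <- compareContinuous(x, y)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      cluster1 = sprintf("%.2f (%.2f)", mean(x), sd(x)),
      cluster2 = sprintf("%.2f (%.2f)", mean(y), sd(y)),
      mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
      test = res$name, statistic = res$statistic, p = res$p,
      normal = res$normal, stringsAsFactors = FALSE)
  }
  for (v in catVars) {
    tab <- table(labels, droplevels(factor(cohort[[v]])))
    res <- chiSquare(tab)
    cnt <- function(i) paste(sprintf("%s:%d", colnames(tab), tab[i, ]),
                             collapse = " ")
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      cluster1 = cnt(1), cluster2 = cnt(2),
      mean1 = NA_real_, sd1 = NA_real_, mean2 = NA_real_, sd2 = NA_real_,
      test = res$name, statistic = res$statistic, p = res$p,
      normal = NA_character_, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (adjust) report$p_adjusted <- p.adjust(report$p, "BH")
  report
}

#' @importFrom stats ave
NULL
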