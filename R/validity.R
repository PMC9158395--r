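# Cluster-validity indices and the majority-vote machinery.

validityIndexNames <- c("ch", "silhouette", "db", "dunn", "cindex",
                        "mcclain", "gap", "hartigan", "kl", "ratkowsky",
                        "ballhall", "pointbiserial", "tracew")

indexOrientations <- c(
  ch = "max", silhouette = "max", db = "min", dunn = "max", cindex = "min",
  mcclain = "min", gap = "gap-oneSE", hartigan = "elbow-diff",
  kl = "max", ratkowsky = "max", ballhall = "elbow-diff",
  pointbiserial = "max", tracew = "elbow-2nd")

clusterStats <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  centers <- do.call(rbind, lapply(ks, function(j)
    colMeans(x[labels == j, , drop = FALSE])))
  sizes <- vapply(ks, function(j) sum(labels == j), integer(1))
  grand <- colMeans(x)
  W <- sum(vapply(seq_along(ks), function(i)
    sum(sweep(x[labels == ks[i], , drop = FALSE], 2, centers[i, ])^2), 0))
  B <- sum(sizes * rowSums(sweep(centers, 2, grand)^2))
  list(k = length(ks), n = nrow(x), p = ncol(x), sizes = sizes,
       centers = centers, grand = grand, W = W, B = B, labels = labels)
}

silhouetteValues <- function(D, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  if (length(ks) < 2L) return(rep(NA_real_, n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != labels[i]], function(j)
      mean(D[i, labels == j]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

#' Cluster-validity criterion value
#'
#' Computes one of the thirteen supported validity indices for a given
#' labeling: Calinski-Harabasz (`ch`), mean silhouette (`silhouette`),
#' Davies-Bouldin (`db`), Dunn (`dunn`), C-index (`cindex`), McClain-Rao
#' (`mcclain`), gap statistic (`gap`), Hartigan (`hartigan`),
#' Krzanowski-Lai (`kl`), Ratkowsky-Lance (`ratkowsky`), Ball-Hall
#' (`ballhall` = W/k, voted on by successive differences), point-biserial
#' (`pointbiserial`) and trace-W (`tracew`, voted on by the elbow).
#' `indexOrientation()` reports how each index's per-k values are turned
#' into a vote. An index that is undefined for the labeling (e.g. a
#' degenerate single cluster for between/within ratios) returns `NA`
#' (abstention).
#'
#' Context-dependent indices need neighbouring-k information through
#' `context`: `hartigan` needs `wssNext` (total within-SS at k + 1), `kl`
#' needs `wssPrev` and `wssNext`, `gap` needs `refLogW` (log reference
#' within-SS draws for this k).
#'
#' @param x subjects x features matrix.
#' @param labels integer cluster labels.
#' @param index index name.
#' @param context list of neighbouring-k quantities (see above).
#' @param D optional precomputed distance matrix.
#' @return scalar criterion value, or `NA` if the index abstains.
#' @export
validityIndex <- function(x, labels, index, context = list(), D = NULL) {
  index <- match.arg(index, validityIndexNames)
  x <- as.matrix(x)
  st <- clusterStats(x, labels)
  k <- st$k; n <- st$n; W <- st$W; B <- st$B
  needD <- index %in% c("silhouette", "db", "dunn", "cindex", "mcclain",
                        "pointbiserial")
  if (needD && is.null(D)) D <- as.matrix(dist(x))
  val <- tryCatch(switch(index,
    ch = if (k < 2L || W <= 0) NA_real_
         else (B / (k - 1)) / (W / (n - k)),
    silhouette = if (k < 2L) NA_real_ else mean(silhouetteValues(D, labels)),
    db = {
      if (k < 2L) return(NA_real_)
      S <- vapply(seq_len(k), function(j) {
        rows <- labels == j
        mean(sqrt(rowSums(sweep(x[rows, , drop = FALSE], 2,
                                st$centers[j, ])^2)))
      }, 0)
      M <- as.matrix(dist(st$centers))
      if (any(M[upper.tri(M)] == 0)) return(NA_real_)
      mean(vapply(seq_len(k), function(j)
        max(((S[j] + S[-j]) / M[j, -j])), 0))
    },
    dunn = {
      if (k < 2L) return(NA_real_)
      diam <- max(vapply(seq_len(k), function(j) {
        d <- D[labels == j, labels == j, drop = FALSE]
        if (length(d) > 1) max(d) else 0
      }, 0))
      if (diam == 0) return(NA_real_)
      sep <- min(vapply(seq_len(k - 1), function(i)
        min(vapply((i + 1):k, function(j)
          min(D[labels == i, labels == j, drop = FALSE]), 0)), 0))
      sep / diam
    },
    cindex = {
      within <- outer(labels, labels, "==")[upper.tri(D)]
      dv <- D[upper.tri(D)]
      nw <- sum(within)
      if (nw == 0L || nw == length(dv)) return(NA_real_)
      sorted <- sort(dv)
      smin <- sum(sorted[seq_len(nw)])
      smax <- sum(sorted[(length(dv) - nw + 1):length(dv)])
      if (smax == smin) return(NA_real_)
      (sum(dv[within]) - smin) / (smax - smin)
    },
    mcclain = {
      within <- outer(labels, labels, "==")[upper.tri(D)]
      dv <- D[upper.tri(D)]
      nw <- sum(within); nb <- sum(!within)
      if (nw == 0L || nb == 0L || sum(dv[!within]) == 0) return(NA_real_)
      (sum(dv[within]) / nw) / (sum(dv[!within]) / nb)
    },
    gap = {
      if (is.null(context$refLogW))
        stop("gap needs context$refLogW (log reference within-SS draws)")
      mean(context$refLogW) - log(W)
    },
    hartigan = {
      if (is.null(context$wssNext))
        stop("hartigan needs context$wssNext")
      if (context$wssNext <= 0) return(NA_real_)
      (W / context$wssNext - 1) * (n - k - 1)
    },
    kl = {
      if (is.null(context$wssPrev) || is.null(context$wssNext))
        stop("kl needs context$wssPrev and context$wssNext")
      p <- st$p
      diffK <- (k - 1)^(2 / p) * context$wssPrev - k^(2 / p) * W
      diffN <- k^(2 / p) * W - (k + 1)^(2 / p) * context$wssNext
      if (diffN == 0) return(NA_real_)
      abs(diffK) / abs(diffN)
    },
    ratkowsky = {
      if (k < 2L) return(NA_real_)
      bj <- colSums(st$sizes * sweep(st$centers, 2, st$grand)^2)
      tj <- colSums(sweep(x, 2, st$grand)^2)
      if (any(tj == 0)) return(NA_real_)
      mean(sqrt(bj / tj)) / sqrt(k)
    },
    ballhall = W / k,
    pointbiserial = {
      within <- outer(labels, labels, "==")[upper.tri(D)]
      dv <- D[upper.tri(D)]
      if (var(as.numeric(within)) == 0 || var(dv) == 0) return(NA_real_)
      cor(dv, as.numeric(!within))
    },
    tracew = W
  ), error = function(e) NA_real_)
  if (length(val) != 1L || !is.finite(val)) NA_real_ else val
}

#' @rdname validityIndex
#' @export
indexOrientation <- function(index) {
  index <- match.arg(index, validityIndexNames)
  indexOrientations[[index]]
}

#' Criterion values and per-index votes over a k range
#'
#' Fits k-means for k = 1 .. max(kRange) + 1 (the flanking fits feed the
#' elbow-type indices), evaluates the full 13-index suite at each candidate
#' k, and derives each index's nominated k. The gap statistic uses
#' `gapRefs` uniform reference draws over the feature-wise bounding box and
#' the one-standard-error rule.
#'
#' @param x subjects x features (standardized) matrix.
#' @param kRange candidate cluster numbers (default 2:8).
#' @param seed master RNG seed for all fits and reference draws.
#' @param nInit k-means++ restarts for data fits (reference fits use 5).
#' @param gapRefs number of gap-statistic reference datasets.
#' @return list: `criteria` (13 x |kRange| value matrix), `votes` (named,
#'   NA = abstain), `wss` (total within-SS for k = 1 .. max + 1), `fits`
#'   (k-means fits indexed by k), `gapSe` (gap standard errors).
#' @export
computeCriteria <- function(x, kRange = 2:8, seed = 1, nInit = 50,
                            gapRefs = 50) {
  x <- as.matrix(x)
  n <- nrow(x)
  kRange <- sort(as.integer(kRange))
  kmax <- max(kRange)
  if (min(kRange) < 2L) stop("candidate k must start at 2")
  if (kmax + 1L >= n) stop("kRange too large for ", n, " subjects")
  D <- as.matrix(dist(x))
  fitK <- 1:(kmax + 1L)
  fits <- lapply(fitK, function(k)
    kmeansFit(x, k, seed = subSeed(seed, paste0("fit", k)), nInit = nInit))
  names(fits) <- fitK
  wss <- vapply(fits, `[[`, 0, "wss")
  names(wss) <- fitK

  # gap statistic reference distribution: uniform over the bounding box
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  gapK <- min(kRange):(kmax + 1L)
  refLogW <- matrix(NA_real_, gapRefs, length(gapK),
                    dimnames = list(NULL, gapK))
  for (b in seq_len(gapRefs)) {
    bs <- subSeed(seed, paste0("gapref", b))
    ref <- withSeed(bs, matrix(runif(n * ncol(x), rep(lo, each = n),
                                     rep(hi, each = n)), n, ncol(x)))
    for (k in gapK)
      refLogW[b, as.character(k)] <-
        log(kmeansFit(ref, k, seed = subSeed(bs, paste0("k", k)),
                      nInit = 5)$wss)
  }
  gapVal <- vapply(gapK, function(k)
    mean(refLogW[, as.character(k)]) - log(wss[[as.character(k)]]), 0)
  gapSe <- vapply(gapK, function(k)
    sd(refLogW[, as.character(k)]) * sqrt(1 + 1 / gapRefs), 0)
  names(gapVal) <- names(gapSe) <- gapK

  criteria <- matrix(NA_real_, length(validityIndexNames), length(kRange),
                     dimnames = list(validityIndexNames, kRange))
  for (k in kRange) {
    lab <- fits[[as.character(k)]]$labels
    ctx <- list(wssPrev = wss[[as.character(k - 1L)]],
                wssNext = wss[[as.character(k + 1L)]],
                refLogW = refLogW[, as.character(k)])
    for (idx in validityIndexNames)
      criteria[idx, as.character(k)] <-
        validityIndex(x, lab, idx, context = ctx, D = D)
  }

  votes <- vapply(validityIndexNames, function(idx) {
    vals <- criteria[idx, ]
    if (all(is.na(vals))) return(NA_integer_)
    switch(indexOrientations[[idx]],
      "max" = kRange[which.max(vals)],
      "min" = kRange[which.min(vals)],
      "elbow-diff" = {
        # largest drop of the criterion from k - 1 to k
        prev <- switch(idx,
          hartigan = vapply(kRange, function(k) {
            wp <- wss[[as.character(k - 1L)]]
            if (k - 1L < 1L || wss[[as.character(k)]] <= 0) NA_real_
            else (wp / wss[[as.character(k)]] - 1) * (n - (k - 1) - 1)
          }, 0),
          ballhall = vapply(kRange, function(k)
            wss[[as.character(k - 1L)]] / (k - 1), 0))
        drop <- prev - vals
        if (all(is.na(drop))) NA_integer_ else kRange[which.max(drop)]
      },
      "elbow-2nd" = {
        second <- vapply(kRange, function(k)
          (wss[[as.character(k - 1L)]] - wss[[as.character(k)]]) -
            (wss[[as.character(k)]] - wss[[as.character(k + 1L)]]), 0)
        kRange[which.max(second)]
      },
      "gap-oneSE" = {
        pick <- NA_integer_
        for (k in kRange) {
          if (gapVal[[as.character(k)]] >=
              gapVal[[as.character(k + 1L)]] - gapSe[[as.character(k + 1L)]]) {
            pick <- k; break
          }
        }
        if (is.na(pick)) max(kRange) else pick
      })
  }, integer(1))

  list(criteria = criteria, votes = votes, wss = wss, fits = fits,
       gap = gapVal, gapSe = gapSe)
}
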