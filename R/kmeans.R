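#' k-means with k-means++ seeding and restarts
#'
#' Lloyd iterations from k-means++ initial centers, repeated `nInit` times;
#' the restart with the lowest total within-cluster sum of squares wins.
#' Convergence when assignments stop changing or the maximum centroid shift
#' falls below `tol`. If a cluster empties during iteration its centroid is
#' re-seeded at the point farthest from its assigned center, so every
#' returned cluster is nonempty.
#'
#' @param x subjects x features numeric matrix.
#' @param k number of clusters (k = 1 and k = n are allowed as degenerate
#'   fits).
#' @param seed RNG seed for the initializations.
#' @param nInit number of k-means++ restarts.
#' @param maxIter Lloyd iteration cap per restart.
#' @param tol centroid-shift convergence tolerance.
#' @return list with `labels`, `centers`, `wss` (total within-cluster SS),
#'   `iter` (iterations of the winning restart).
#' @export
kmeansFit <- function(x, k, seed = 1, nInit = 50, maxIter = 100,
                      tol = 1e-8) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in 1..n")
  if (k == 1L) {
    ctr <- matrix(colMeans(x), 1, ncol(x))
    return(list(labels = rep(1L, n), centers = ctr,
                wss = sum(sweep(x, 2, ctr)^2), iter = 0L))
  }
  rs <- rowSums(x^2)
  seq_n <- seq_len(n)
  # squared distances of all points to each center row
  dist2 <- function(centers)
    pmax(outer(rs, rowSums(centers^2), "+") - 2 * tcrossprod(x, centers), 0)
  best <- NULL
  withSeed(seed, {
    for (init in seq_len(nInit)) {
      # k-means++ seeding, O(nk): track running min distance
      idx <- sample.int(n, 1L)
      centers <- x[idx, , drop = FALSE]
      dmin <- pmax(rs + sum(centers^2) - 2 * drop(x %*% centers[1L, ]), 0)
      while (nrow(centers) < k) {
        pick <- if (sum(dmin) > 0) sample.int(n, 1L, prob = dmin)
                else sample.int(n, 1L)
        cc <- x[pick, , drop = FALSE]
        centers <- rbind(centers, cc)
        dmin <- pmin(dmin, pmax(rs + sum(cc^2) - 2 * drop(x %*% cc[1L, ]), 0))
      }
      d2 <- dist2(centers)
      lab <- max.col(-d2, ties.method = "first")
      iter <- 0L
      repeat {
        iter <- iter + 1L
        cnt <- tabulate(lab, k)
        newCenters <- centers
        present <- cnt > 0L
        sums <- rowsum(x, lab)
        newCenters[present, ] <- sums / cnt[present]
        if (any(!present)) {
          # empty-cluster policy: reseed at the farthest point
          for (j in which(!present)) {
            far <- which.max(apply(dist2(newCenters), 1, min))
            newCenters[j, ] <- x[far, ]
          }
        }
        d2 <- dist2(newCenters)
        newLab <- max.col(-d2, ties.method = "first")
        shift <- max(rowSums((newCenters - centers)^2))
        centers <- newCenters
        done <- identical(newLab, lab) || shift < tol || iter >= maxIter
        lab <- newLab
        if (done) break
      }
      wss <- sum(d2[cbind(seq_n, lab)])
      if (is.null(best) || wss < best$wss - 1e-12)
        best <- list(labels = lab, centers = centers, wss = wss,
                     iter = iter)
    }
  })
  # exact cluster means and within-SS of the final assignment
  cnt <- tabulate(best$labels, k)
  best$centers[cnt > 0L, ] <- rowsum(x, best$labels) / cnt[cnt > 0L]
  best$wss <- withinSSOf(x, best$labels)
  best
}

# Total within-cluster sum of squares of a labeling.
withinSSOf <- function(x, labels) {
  sum(vapply(unique(labels), function(j) {
    rows <- which(labels == j)
    sum(sweep(x[rows, , drop = FALSE], 2,
              colMeans(x[rows, , drop = FALSE]))^2)
  }, 0))
}
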