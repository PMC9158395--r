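# Independent brute-force oracles used to validate the analytical code.
# Everything here is written naively (double loops, direct formulas) and
# shares no code with the package internals it checks.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracleWSS <- function(x, labels) {
  total <- 0
  for (j in unique(labels)) {
    rows <- x[labels == j, , drop = FALSE]
    ctr <- colMeans(rows)
    for (i in seq_len(nrow(rows))) total <- total + sum((rows[i, ] - ctr)^2)
  }
  total
}

oracleBSS <- function(x, labels) {
  grand <- colMeans(x)
  total <- 0
  for (j in unique(labels)) {
    rows <- x[labels == j, , drop = FALSE]
    total <- total + nrow(rows) * sum((colMeans(rows) - grand)^2)
  }
  total
}

oracleCH <- function(x, labels) {
  k <- length(unique(labels)); n <- nrow(x)
  (oracleBSS(x, labels) / (k - 1)) / (oracleWSS(x, labels) / (n - k))
}

oracleSilhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) euclid(x[i, ], x[j, ])))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      other <- which(labels == cl)
      b <- min(b, mean(sapply(other, function(j) euclid(x[i, ], x[j, ]))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracleDB <- function(x, labels) {
  ks <- sort(unique(labels))
  S <- sapply(ks, function(j) {
    rows <- x[labels == j, , drop = FALSE]
    ctr <- colMeans(rows)
    mean(apply(rows, 1, function(r) euclid(r, ctr)))
  })
  ctrs <- t(sapply(ks, function(j) colMeans(x[labels == j, , drop = FALSE])))
  mean(sapply(seq_along(ks), function(j) {
    max(sapply(setdiff(seq_along(ks), j), function(l)
      (S[j] + S[l]) / euclid(ctrs[j, ], ctrs[l, ])))
  }))
}

oracleDunn <- function(x, labels) {
  ks <- sort(unique(labels))
  diam <- 0
  for (j in ks) {
    rows <- which(labels == j)
    for (a in rows) for (b in rows)
      diam <- max(diam, euclid(x[a, ], x[b, ]))
  }
  sep <- Inf
  for (j in ks) for (l in ks) if (j < l)
    for (a in which(labels == j)) for (b in which(labels == l))
      sep <- min(sep, euclid(x[a, ], x[b, ]))
  sep / diam
}

oracleCindex <- function(x, labels) {
  n <- nrow(x)
  dwithin <- c(); dall <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- euclid(x[i, ], x[j, ])
    dall <- c(dall, d)
    if (labels[i] == labels[j]) dwithin <- c(dwithin, d)
  }
  nw <- length(dwithin)
  sorted <- sort(dall)
  smin <- sum(sorted[1:nw])
  smax <- sum(sorted[(length(dall) - nw + 1):length(dall)])
  (sum(dwithin) - smin) / (smax - smin)
}

oracleMcClain <- function(x, labels) {
  n <- nrow(x)
  dw <- c(); db <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- euclid(x[i, ], x[j, ])
    if (labels[i] == labels[j]) dw <- c(dw, d) else db <- c(db, d)
  }
  mean(dw) / mean(db)
}

oracleRatkowsky <- function(x, labels) {
  k <- length(unique(labels))
  grand <- colMeans(x)
  cvals <- sapply(seq_len(ncol(x)), function(v) {
    bj <- 0
    for (j in unique(labels)) {
      rows <- which(labels == j)
      bj <- bj + length(rows) * (mean(x[rows, v]) - grand[v])^2
    }
    tj <- sum((x[, v] - grand[v])^2)
    sqrt(bj / tj)
  })
  mean(cvals) / sqrt(k)
}

oraclePointBiserial <- function(x, labels) {
  n <- nrow(x)
  dv <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dv <- c(dv, euclid(x[i, ], x[j, ]))
    between <- c(between, as.numeric(labels[i] != labels[j]))
  }
  cor(dv, between)
}

oracleHartigan <- function(wk, wk1, n, k) (wk / wk1 - 1) * (n - k - 1)

oracleKL <- function(wprev, wk, wnext, k, p) {
  diffK <- (k - 1)^(2 / p) * wprev - k^(2 / p) * wk
  diffN <- k^(2 / p) * wk - (k + 1)^(2 / p) * wnext
  abs(diffK) / abs(diffN)
}

oracleGap <- function(wk, refLogW) mean(refLogW) - log(wk)

# All assignments of n points to exactly k nonempty clusters (canonical
# first-occurrence labeling to avoid duplicates).
enumeratePartitions <- function(n, k) {
  out <- list()
  recur <- function(lab, used) {
    i <- length(lab) + 1L
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- lab
      return(invisible())
    }
    for (j in seq_len(min(used + 1L, k)))
      recur(c(lab, j), max(used, j))
  }
  recur(integer(0), 0L)
  out
}

bestPartitionWSS <- function(x, k) {
  min(sapply(enumeratePartitions(nrow(x), k),
             function(lab) oracleWSS(x, lab)))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mwExactP <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  pooled <- c(x, y)
  uOf <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- uOf(seq_len(nx))
  us <- combn(n, nx, uOf)
  mu <- nx * (n - nx) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

makeBlobs <- function(nPer, centers, sdWithin = 0.2, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(j)
    matrix(rnorm(nPer * ncol(centers), mean = rep(centers[j, ], each = nPer),
                 sd = sdWithin), nPer, ncol(centers))))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = nPer))
}

# A small, fast cohort configuration for module-level tests.
smallConfig <- function(...) {
  defaultCohortConfig(nEnrolled = 24L, nComplete = 20L,
                      clusterSizes = c(10L, 10L), ...)
}

smallGrid <- function(tp = 60L) gridSpec(nTimepoints = tp)
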