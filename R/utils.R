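# Internal helpers: seed handling, truncated-normal machinery, fingerprints.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic sub-seed from a master seed and a string key (polynomial
# hash), so per-subject streams are independent of generation order.
subSeed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (cc in utf8ToInt(as.character(key)))
    h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# Mills ratio, stable in the far tail.
millsRatio <- function(a) dnorm(a) / pnorm(a, lower.tail = FALSE)

# Mean of a normal(mu, sigma) truncated below at 0.
trunc0Mean <- function(mu, sigma) {
  a <- -mu / sigma
  mu + sigma * millsRatio(a)
}

# Latent mean such that the zero-truncated normal with SD `sigma` has the
# requested mean. Monotone in mu, solved by uniroot.
trunc0LatentMean <- function(target, sigma) {
  if (target / sigma > 6) return(target)  # truncation negligible
  uniroot(function(mu) trunc0Mean(mu, sigma) - target,
          c(-8 * sigma, target + sigma), tol = 1e-10)$root
}

# Quantile function of the zero-truncated normal.
qtrunc0 <- function(u, mu, sigma) {
  p0 <- pnorm(0, mu, sigma)
  qnorm(p0 + u * (1 - p0), mu, sigma)
}

# Cheap content fingerprint for run manifests (length, sum, sum of squares
# of the numeric content). Not cryptographic; collision-unlikely for the
# determinism checks it supports.
fingerprintOf <- function(x) {
  v <- x
  if (is.data.frame(v))
    v <- unlist(lapply(v, function(col)
      if (is.numeric(col)) col else as.integer(as.factor(col))),
      use.names = FALSE)
  v <- suppressWarnings(as.numeric(unlist(v, use.names = FALSE)))
  v <- v[is.finite(v)]
  sprintf("n%d:%.10e:%.10e", length(v), sum(v), sum(v * v))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects;
#' 1 = identical partitions, ~0 = chance. Used to quantify recovery of the
#' planted cluster structure.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return scalar ARI.
#' @export
adjustedRand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  mclust::adjustedRandIndex(a, b)
}
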