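#' Residualize a variable on age and sex
#'
#' Ordinary least squares of `values` on an intercept, age and binary sex;
#' returns the residuals. A covariate that is constant (collinear with the
#' intercept) is dropped with a warning; any other rank deficiency is an
#' error.
#'
#' @param values numeric response vector, no missing values.
#' @param age numeric covariate (years).
#' @param sex binary covariate; factors/characters are coded female = 1.
#' @return residual vector, orthogonal to the retained covariates.
#' @export
residualize <- function(values, age, sex) {
  n <- length(values)
  if (length(age) != n || length(sex) != n)
    stop("values, age and sex must have equal length")
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(values) || anyNA(age) || anyNA(sex))
    stop("missing values: residualization is complete-case only")
  if (is.factor(sex) || is.character(sex))
    sex <- as.numeric(as.character(sex) == "female")
  X <- cbind(intercept = 1, age = as.numeric(age), sex = as.numeric(sex))
  const <- apply(X[, -1, drop = FALSE], 2, function(col) var(col) == 0)
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  fit <- lm.fit(X, values)
  if (fit$rank < ncol(X))
    stop("rank-deficient design in residualization")
  fit$residuals
}

# Mid-ranks (average ranks for ties).
midRank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; the two-sided p-value uses the
#' t approximation `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom (adequate in the n ~ 100 regime this pipeline targets).
#'
#' @param x,y numeric vectors, n >= 5, no missing values.
#' @return list with `rho`, `p` and `n`.
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 5L) stop("need at least 5 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in spearmanRho")
  rx <- midRank(x); ry <- midRank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop("undefined correlation: zero rank variance")
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0
       else 2 * pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2,
                   lower.tail = FALSE)
  list(rho = rho, p = p, n = n)
}

#' Age/sex-adjusted Spearman association matrix
#'
#' Builds the symmetric Spearman rho (and p-value) matrix over the given
#' variables, optionally residualizing every variable on age and sex first
#' (the covariates themselves are excluded from the matrix). Significance
#' is conventionally read at p < 0.05 without multiplicity correction,
#' matching how such basic association matrices are reported.
#'
#' @param features data.frame of numeric variables (complete cases only).
#' @param adjust residualize on age/sex before ranking?
#' @param age,sex covariate vectors aligned with `features` rows (required
#'   when `adjust = TRUE`).
#' @return an [AssociationMatrix-class].
#' @export
associationMatrix <- function(features, adjust = TRUE, age = NULL,
                              sex = NULL) {
  num <- vapply(features, is.numeric, logical(1))
  features <- features[, num, drop = FALSE]
  if (anyNA(features))
    stop("missing values in feature table: filter to complete cases ",
         "upstream")
  M <- as.matrix(features)
  if (adjust) {
    if (is.null(age) || is.null(sex))
      stop("adjust = TRUE needs age and sex covariates")
    M <- apply(M, 2, residualize, age = age, sex = sex)
  }
  p <- ncol(M)
  rho <- diag(1, p)
  pv <- matrix(0, p, p)
  dimnames(rho) <- dimnames(pv) <- list(colnames(M), colnames(M))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    s <- spearmanRho(M[, i], M[, j])
    rho[i, j] <- rho[j, i] <- s$rho
    pv[i, j] <- pv[j, i] <- s$p
  }
  new("AssociationMatrix", rho = rho, p = pv, adjusted = adjust)
}
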