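test_that("residualization removes covariate effects exactly", {
  # perfectly explained response -> zero residuals
  age <- c(1, 2, 3, 4); sex <- c(0, 0, 1, 1)
  expect_equal(residualize(2 * age, age, sex), rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(residualize(c(1, 2, 3, 4), age, sex), rep(0, 4),
               ignore_attr = TRUE)
  # independent response -> centering (up to the sampled fit)
  set.seed(2)
  v <- rnorm(50); a <- rnorm(50); s <- rbinom(50, 1, 0.5)
  r <- residualize(v, a, s)
  expect_lt(abs(sum(r * (a - mean(a)))), 1e-8 * 50 * sd(v))
  expect_lt(abs(sum(r * (s - mean(s)))), 1e-8 * 50 * sd(v))
  expect_lt(abs(mean(r)), 1e-10)
  # oracle: residuals from the normal equations
  X <- cbind(1, a, s)
  beta <- solve(t(X) %*% X, t(X) %*% v)
  expect_equal(r, as.vector(v - X %*% beta), ignore_attr = TRUE)
  # constant covariate dropped with a warning; factor sex accepted
  expect_warning(residualize(v, a, rep(1, 50)), "constant")
  expect_equal(residualize(v, a, factor(ifelse(s == 1, "female", "male"),
                                        levels = c("female", "male"))),
               r, ignore_attr = TRUE)
})

test_that("spearmanRho reproduces textbook rank correlations", {
  x <- c(0.3, 1.1, 2.7)
  expect_equal(spearmanRho(c(x, 3, 4), exp(c(x, 3, 4)))$rho, 1)
  expect_equal(spearmanRho(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))$rho, -1)
  # 1 - 6*sum(d^2)/(n(n^2-1)) with sum(d^2) = 4 -> 0.8
  s <- spearmanRho(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(s$rho, 0.8)
  # rho agrees with stats::cor; p with the t approximation
  set.seed(4)
  a <- rnorm(30); b <- a + rnorm(30)
  s2 <- spearmanRho(a, b)
  expect_equal(s2$rho, cor(a, b, method = "spearman"))
  tt <- s2$rho * sqrt(28 / (1 - s2$rho^2))
  expect_equal(s2$p, 2 * pt(abs(tt), 28, lower.tail = FALSE))
  expect_error(spearmanRho(rep(1, 10), rnorm(10)), "zero rank variance")
})

test_that("association matrix is symmetric with unit diagonal and flags duplicates", {
  set.seed(6)
  tbl <- data.frame(a = rnorm(40), b = rnorm(40))
  tbl$c <- tbl$a  # duplicated variable
  am <- associationMatrix(tbl, adjust = FALSE)
  rho <- rhoValues(am)
  expect_equal(diag(rho), rep(1, 3), ignore_attr = TRUE)
  expect_equal(rho, t(rho))
  expect_equal(rho["a", "c"], 1)
  expect_error(associationMatrix(data.frame(a = c(1, NA, 3, 4, 5),
                                            b = rnorm(5)), adjust = FALSE),
               "complete cases")
})

test_that("adjustment is a no-op when no covariate effect exists", {
  set.seed(8)
  n <- 60
  tbl <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  age <- rnorm(n, 50, 10); sex <- factor(rep(c("female", "male"), n / 2))
  plain <- rhoValues(associationMatrix(tbl, adjust = FALSE))
  adj <- rhoValues(associationMatrix(tbl, adjust = TRUE, age = age,
                                     sex = sex))
  expect_equal(adj, plain, tolerance = 0.15)
})

test_that("planted metabolic correlations are detected, cortisol stays unlinked", {
  cfg <- defaultCohortConfig(seed = 31)
  co <- filterComplete(generateCohort(cfg))
  am <- associationMatrix(co[, metabolicVars()], adjust = TRUE,
                          age = co$age, sex = co$sex)
  p <- pValues(am)
  core <- setdiff(metabolicVars(), "cortisol")
  offdiag <- p[core, core][upper.tri(p[core, core])]
  expect_true(all(offdiag < 0.001))
  cortP <- p["cortisol", core]
  expect_gte(sum(cortP > 0.05), 4)
})
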