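test_that("z-scoring normalizes columns with the sample SD", {
  expect_equal(as.vector(zscore(matrix(1:3, ncol = 1))), c(-1, 0, 1))

  x <- matrix(c(2, 4, 4, 4, 5, 5, 7, 9), ncol = 1)
  z <- zscore(x)
  expect_equal(z[1], (2 - 5) / sqrt(32 / 7), tolerance = 1e-12)  # about -1.403

  # idempotence
  z2 <- zscore(z)
  expect_equal(as.vector(z2), as.vector(z), tolerance = 1e-12)

  # columns end up with mean 0, sd 1 to high precision
  set.seed(1)
  big <- zscore(matrix(rnorm(500) * 7 + 3, ncol = 5))
  expect_lt(max(abs(colMeans(big))), 1e-10)
  expect_lt(max(abs(apply(big, 2, sd) - 1)), 1e-10)

  bad <- data.frame(a = rnorm(10), flat = rep(2, 10))
  expect_error(zscore(bad), "flat")
})

test_that("outlier screens flag extreme subjects without deleting them", {
  set.seed(5)
  z <- zscore(matrix(rnorm(400), ncol = 2))
  z[abs(z) > 2] <- 1.9  # force everything inside (-2, 2)
  s <- screen_outliers(z)
  expect_false(any(s$univariate))

  z1 <- z; z1[7, 1] <- 5
  s1 <- screen_outliers(z1)
  expect_true(s1$univariate[7])

  # planted multivariate outlier under near-identity covariance:
  # squared Mahalanobis distance about 3.5^2 + 3.5^2 = 24.5 > chi2_2 cutoff
  z2 <- z; z2[11, ] <- c(3.5, -3.5)
  s2 <- screen_outliers(z2)
  expect_true(s2$multivariate[11])
  expect_equal(s2$d2[11], 24.5, tolerance = 0.2 * 24.5)
  expect_equal(s2$cutoff, qchisq(0.999, 2))

  dup <- cbind(z[, 1], z[, 1])
  expect_error(screen_outliers(dup), "singular|collinear")
  expect_error(screen_outliers(z[1:2, ]), "more subjects")
})

test_that("ML factor analysis recovers a noiseless one-factor model", {
  lam <- c(0.75, 0.62, 0.66, 0.82, 0.59)
  R <- lam %*% t(lam); diag(R) <- 1
  sol <- ml_efa(R, 1, 139)
  expect_lt(max(abs(sol$loadings[, 1] - lam)), 1e-4)
  expect_lt(sol$fit$RMSR, 1e-5)
  expect_equal(sol$var_explained, mean(lam^2), tolerance = 1e-4)
  # uniqueness identity on the fitted model
  expect_lt(max(abs(sol$uniquenesses - (1 - rowSums(sol$loadings^2)))), 1e-4)
})

test_that("ML factor analysis finds no common variance in independent data", {
  sol <- ml_efa(diag(5), 1, 500)
  expect_lt(sol$var_explained, 0.05)
  expect_lt(sol$fit$RMSR, 1e-6)
  expect_error(ml_efa(diag(5), 5, 500), "n_factors")
  expect_error(ml_efa(matrix(1:6, 2, 3), 1, 100), "square")
})

test_that("factors are oriented with their largest loading positive", {
  lam <- c(0.8, 0.7, 0.6)
  R <- lam %*% t(lam); diag(R) <- 1
  sol <- ml_efa(R, 1, 200)
  expect_true(sol$loadings[which.max(abs(sol$loadings[, 1])), 1] > 0)
})

test_that("fit indices follow their defining formulas", {
  p <- 5
  zero_resid <- matrix(0, p, p)
  perfect <- fit_indices(5, 5, 200, zero_resid, null_chisq = 500, null_df = 10)
  expect_equal(perfect$RMSR, 0)
  expect_equal(perfect$RMSEA, 0)

  # chi-square twice the df: RMSEA = 1/sqrt(n-1)
  f <- fit_indices(2 * 5, 5, 101, zero_resid, null_chisq = 500, null_df = 10)
  expect_equal(f$RMSEA, 1 / sqrt(100))

  # fitted model no better than the independence model: TLI = 0
  f0 <- fit_indices(50, 5, 200, zero_resid, null_chisq = 100, null_df = 10)
  expect_equal(f0$TLI, 0)

  # saturated model: indices undefined
  sat <- fit_indices(NA, 0, 200, zero_resid)
  expect_true(is.na(sat$RMSEA) && is.na(sat$TLI))
})

test_that("parallel analysis retains the generating factor count", {
  x1 <- one_factor_sample(500, rep(0.7, 5), seed = 61)
  pa1 <- parallel_analysis(x1, n_permutations = 200, seed = 62)
  expect_equal(pa1$n_factors, 1L)

  # two orthogonal factors with three strong markers each
  set.seed(63)
  f1 <- rnorm(500); f2 <- rnorm(500)
  x2 <- cbind(sapply(rep(0.8, 3), function(l) l * f1 + sqrt(1 - l^2) * rnorm(500)),
              sapply(rep(0.8, 3), function(l) l * f2 + sqrt(1 - l^2) * rnorm(500)))
  pa2 <- parallel_analysis(x2, n_permutations = 200, seed = 64)
  expect_equal(pa2$n_factors, 2L)

  # independent columns: nothing should systematically beat its null
  set.seed(65)
  x0 <- matrix(rnorm(500 * 5), ncol = 5)
  pa0 <- parallel_analysis(x0, n_permutations = 200, seed = 66, summary = "p95")
  expect_equal(pa0$n_factors, 0L)

  expect_error(parallel_analysis(x1, n_permutations = 50), "100")
  expect_error(parallel_analysis(x1[1:4, ]), "more subjects")
})

test_that("parallel analysis is invariant to column order and monotone rescaling", {
  x <- one_factor_sample(300, c(0.7, 0.6, 0.8, 0.65, 0.5), seed = 71)
  base <- parallel_analysis(x, n_permutations = 200, seed = 72)$n_factors
  perm <- parallel_analysis(x[, c(3, 1, 5, 2, 4)], n_permutations = 200,
                            seed = 72)$n_factors
  scaled <- x; scaled[, 2] <- scaled[, 2] * 13 + 5
  resc <- parallel_analysis(scaled, n_permutations = 200, seed = 72)$n_factors
  expect_equal(perm, base)
  expect_equal(resc, base)
})

test_that("regression factor scores track the generating latent", {
  # noiseless one-factor data: scores recover the latent almost exactly
  set.seed(81)
  g <- rnorm(400)
  lam <- c(0.9, 0.8, 0.85, 0.75)
  x <- sapply(lam, function(l) l * g + sqrt(1 - l^2) * rnorm(400, sd = 0.01))
  sol <- ml_efa(cor(x), 1, 400)
  sc <- factor_scores(sol, x)
  expect_gt(abs(cor(sc[, 1], g)), 0.999)

  # equal loadings: scores proportional to the row mean of z-scores
  # (exactly so under the model-implied equicorrelation matrix)
  xe <- one_factor_sample(300, rep(0.7, 4), seed = 82)
  Re <- 0.7^2 * (matrix(1, 4, 4) - diag(4)) + diag(4)
  sole <- ml_efa(Re, 1, 300)
  sce <- factor_scores(sole, xe)
  expect_gt(abs(cor(sce[, 1], rowMeans(scale(xe)))), 1 - 1e-10)
})

test_that("bootstrap loading intervals bracket the generating loadings", {
  lam <- c(0.75, 0.62, 0.66, 0.82, 0.59)
  x <- one_factor_sample(139, lam, seed = 91)
  ci <- efa_loading_ci(x, 1, n_boot = 300, seed = 92)
  expect_equal(ci$n_ok, 300)
  covered <- lam >= ci$lower[, 1] & lam <= ci$upper[, 1]
  expect_gte(sum(covered), 4)  # 5 intervals at 90% nominal coverage
})

test_that("residualization removes age and sex structure", {
  set.seed(101)
  n <- 500
  age <- runif(n, 7, 12); sex <- rbinom(n, 1, 0.5)

  # independent scores: essentially unchanged
  s0 <- rnorm(n)
  r0 <- residualize(s0, age, sex)
  expect_gt(cor(r0, s0), 0.99)

  # fully explained scores: nothing left
  r1 <- residualize(2 * age, age, sex)
  expect_lt(max(abs(r1)), 1e-8)

  # residuals orthogonal to all modelled covariates
  s2 <- 0.5 * age + 0.3 * (age - 9.5)^2 + 0.4 * sex + rnorm(n)
  r2 <- residualize(s2, age, sex)
  expect_lt(abs(cor(r2, age)), 1e-10)
  expect_lt(abs(cor(r2, age^2)), 1e-10)
  expect_lt(abs(cor(r2, sex)), 1e-10)

  expect_warning(residualize(s0, age, rep(1, n)), "sex")
})
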