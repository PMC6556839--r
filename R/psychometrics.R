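#' z-score a table of test scores
#'
#' Normalizes every measure to mean 0 and unit sample standard deviation
#' (denominator n-1), the scale on which outlier screens, factor analysis
#' and all standardized regressions operate.
#'
#' @param table Numeric matrix or data frame of subjects x measures (a
#'   `subject` id column, if present, is carried through unchanged).
#' @return Object of the same shape with z-scored measure columns and
#'   attribute `zscored = TRUE`.
#' @export
zscore <- function(table) {
  is_df <- is.data.frame(table)
  id <- NULL
  x <- table
  if (is_df) {
    num <- vapply(table, is.numeric, logical(1))
    id <- table[!num]
    x <- as.matrix(table[num])
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds <= 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds <= 0 | !is.finite(sds)]
    stopf("cannot z-score constant column(s): %s", paste(bad, collapse = ", "))
  }
  z <- scale(x)[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  out <- if (is_df) {
    cbind(id, as.data.frame(z))
  } else z
  attr(out, "zscored") <- TRUE
  out
}

score_matrix <- function(table) {
  if (is.data.frame(table)) as.matrix(table[vapply(table, is.numeric, logical(1))])
  else as.matrix(table)
}

#' Screen for univariate and multivariate outliers
#'
#' On z-scored data, flags subjects with any |z| > 3 (univariate) and
#' subjects whose squared Mahalanobis distance exceeds the chi-square
#' quantile with df = number of measures at the configured tail probability
#' (multivariate). Flags are returned, nothing is deleted.
#'
#' @param table z-scored subjects x measures matrix or data frame.
#' @param level Upper-tail probability for the Mahalanobis cutoff
#'   (default 0.001).
#' @param z_cutoff Absolute z threshold for the univariate screen (default 3).
#' @return List with logical vectors `univariate` and `multivariate` (one
#'   per subject), the squared distances `d2`, and the `cutoff` used.
#' @export
screen_outliers <- function(table, level = 0.001, z_cutoff = 3) {
  z <- score_matrix(table)
  n <- nrow(z); p <- ncol(z)
  if (n <= p) stopf("need more subjects (%d) than measures (%d)", n, p)
  uni <- apply(abs(z) > z_cutoff, 1, any)
  S <- cov(z)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok) stopf("covariance matrix is singular; drop collinear columns before screening")
  d2 <- mahalanobis(z, center = colMeans(z), cov = S)
  cutoff <- qchisq(1 - level, df = p)
  list(univariate = uni, multivariate = d2 > cutoff, d2 = d2, cutoff = cutoff)
}

#' Maximum-likelihood exploratory factor analysis
#'
#' Fits the unrotated normal-theory factor model Sigma = Lambda Lambda' + Psi
#' to a correlation matrix by maximum likelihood (via [stats::factanal];
#' uniquenesses are bounded below at 0.005, so Heywood cases are clamped and
#' reported). Each factor is oriented so its largest-magnitude loading is
#' positive. Fit indices (RMSR, RMSEA, Tucker-Lewis) are computed from the
#' likelihood-ratio statistic and the residual correlations; for a saturated
#' model (df <= 0) they are reported as `NA`.
#'
#' @param corr_matrix Symmetric positive semi-definite correlation matrix.
#' @param n_factors Number of factors, `1 <= n_factors < n_measures`.
#' @param n_obs Number of observations behind the correlation matrix.
#' @param data Optional subjects x measures data (raw or z-scored). When
#'   supplied, regression-method factor scores and, if `n_boot > 0`,
#'   bootstrap 5-95% loading intervals are computed.
#' @param n_boot Bootstrap resamples for loading intervals (default 0 = none;
#'   10000 is the conventional choice).
#' @param seed Seed for the bootstrap.
#' @return A `factor_solution`: loadings, uniquenesses, `var_explained`,
#'   observed eigenvalues, fit indices, optional `scores` and `loading_ci`,
#'   and the names of measures whose uniqueness hit the Heywood bound.
#' @export
ml_efa <- function(corr_matrix, n_factors, n_obs, data = NULL,
                   n_boot = 0, seed = NULL) {
  R <- as.matrix(corr_matrix)
  p <- nrow(R)
  if (ncol(R) != p) stopf("correlation matrix must be square")
  if (max(abs(R - t(R))) > 1e-8) stopf("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-6)) stopf("diagonal of a correlation matrix must be 1")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stopf("correlation matrix is not positive semi-definite")
  }
  if (n_factors < 1 || n_factors >= p) {
    stopf("n_factors must satisfy 1 <= n_factors < %d measures", p)
  }
  fit <- tryCatch(
    factanal(covmat = R, factors = n_factors, n.obs = n_obs, rotation = "none"),
    error = function(e) stopf("factor model did not converge: %s", conditionMessage(e)))
  L <- orient_loadings(unclass(fit$loadings)[, , drop = FALSE])
  psi <- fit$uniquenesses
  heywood <- names(psi)[psi <= 0.005 + 1e-8]
  implied <- L %*% t(L) + diag(psi, p)
  residual <- R - implied
  df <- ((p - n_factors)^2 - p - n_factors) / 2
  chisq <- if (df > 0 && !is.null(fit$STATISTIC)) unname(fit$STATISTIC) else NA_real_
  nullm <- null_model_chisq(R, n_obs)
  idx <- fit_indices(chisq, df, n_obs, residual,
                     null_chisq = nullm$chisq, null_df = nullm$df)
  out <- structure(list(
    n_factors = n_factors,
    loadings = L,
    uniquenesses = psi,
    var_explained = mean(rowSums(L^2)),
    eigenvalues_observed = eigen(R, symmetric = TRUE, only.values = TRUE)$values,
    fit = c(idx, list(chisq = chisq, df = df, converged = fit$converged %||% TRUE)),
    heywood = heywood,
    n_obs = n_obs,
    corr = R
  ), class = "factor_solution")
  if (!is.null(data)) {
    out$scores <- factor_scores(out, data)
    if (n_boot > 0) {
      out$loading_ci <- efa_loading_ci(data, n_factors, n_boot = n_boot, seed = seed)
    }
  }
  out
}

# Orient each factor so its largest-magnitude loading is positive.
orient_loadings <- function(L) {
  for (k in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, k])), k] < 0) L[, k] <- -L[, k]
  }
  L
}

# Bartlett-corrected independence-model chi-square, the baseline for the
# Tucker-Lewis index.
null_model_chisq <- function(R, n_obs) {
  p <- nrow(R)
  list(chisq = -(n_obs - 1 - (2 * p + 5) / 6) * determinant(R, logarithm = TRUE)$modulus[1],
       df = p * (p - 1) / 2)
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("factor_solution: %d factor(s), %d measures, var explained %.2f\n",
              x$n_factors, nrow(x$loadings), x$var_explained))
  print(round(x$loadings, 2))
  cat(sprintf("RMSR %.3f, RMSEA %.3f, TLI %.3f\n",
              x$fit$RMSR, x$fit$RMSEA, x$fit$TLI))
  if (length(x$heywood)) cat("Heywood bound hit:", paste(x$heywood, collapse = ", "), "\n")
  invisible(x)
}

#' Factor-model fit indices
#'
#' RMSR is the root mean square of the off-diagonal residual correlations;
#' RMSEA = sqrt(max(chisq - df, 0) / (df * (n - 1))); the Tucker-Lewis index
#' compares the chi-square/df ratios of the fitted and the independence
#' model, `TLI = (X0/df0 - X1/df1) / (X0/df0 - 1)`.
#'
#' @param likelihood_stat Likelihood-ratio chi-square of the fitted model.
#' @param df_model Model degrees of freedom; indices are `NA` when <= 0.
#' @param n_obs Number of observations.
#' @param residual_matrix Observed-minus-implied correlation matrix.
#' @param null_chisq,null_df Independence-model chi-square and df (needed
#'   for the TLI only).
#' @return List with `RMSR`, `RMSEA`, `TLI`.
#' @export
fit_indices <- function(likelihood_stat, df_model, n_obs, residual_matrix,
                        null_chisq = NULL, null_df = NULL) {
  off <- residual_matrix[upper.tri(residual_matrix)]
  rmsr <- sqrt(mean(off^2))
  if (is.na(df_model) || df_model <= 0 || is.na(likelihood_stat)) {
    return(list(RMSR = rmsr, RMSEA = NA_real_, TLI = NA_real_))
  }
  rmsea <- sqrt(max(likelihood_stat - df_model, 0) / (df_model * (n_obs - 1)))
  tli <- if (!is.null(null_chisq) && !is.null(null_df) && null_df > 0) {
    r0 <- null_chisq / null_df
    r1 <- likelihood_stat / df_model
    (r0 - r1) / (r0 - 1)
  } else NA_real_
  list(RMSR = rmsr, RMSEA = rmsea, TLI = tli)
}

#' Horn-style parallel analysis for factor retention
#'
#' Compares the eigenvalues of the observed correlation matrix to a null
#' distribution obtained by independently permuting the rows of every
#' column (destroying cross-column structure while preserving marginals)
#' and recomputing the eigenvalues. The retained count is the largest k
#' such that each of the first k observed eigenvalues exceeds its null
#' summary (the permutation mean by default; 95th percentile optional).
#'
#' @param data Subjects x measures data (z-scored internally).
#' @param n_permutations Number of column-shuffled datasets (>= 100;
#'   default 10000).
#' @param seed Integer seed.
#' @param summary `"mean"` (default) or `"p95"`.
#' @return A `parallel_analysis` list: `n_factors`, `eigenvalues_observed`,
#'   `null_mean`, `null_p95`, and the summary used.
#' @export
parallel_analysis <- function(data, n_permutations = 10000, seed = NULL,
                              summary = c("mean", "p95")) {
  summary <- match.arg(summary)
  if (n_permutations < 100) stopf("n_permutations must be >= 100")
  x <- score_matrix(data)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stopf("need more subjects (%d) than measures (%d)", n, p)
  z <- scale(x)
  obs <- eigen(cor(z), symmetric = TRUE, only.values = TRUE)$values
  with_rng_seed(seed, {
    null_eigs <- matrix(0, n_permutations, p)
    zz <- z
    for (b in seq_len(n_permutations)) {
      for (j in seq_len(p)) zz[, j] <- z[sample.int(n), j]
      null_eigs[b, ] <- eigen(cor(zz), symmetric = TRUE, only.values = TRUE)$values
    }
    null_mean <- colMeans(null_eigs)
    null_p95 <- apply(null_eigs, 2, quantile, probs = 0.95, names = FALSE)
    ref <- if (summary == "mean") null_mean else null_p95
    above <- obs > ref
    n_factors <- if (above[1]) {
      rle(above)$lengths[1]
    } else 0L
    structure(list(n_factors = as.integer(n_factors),
                   eigenvalues_observed = obs,
                   null_mean = null_mean, null_p95 = null_p95,
                   summary = summary, n_permutations = n_permutations),
              class = "parallel_analysis")
  })
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("parallel_analysis: retain %d factor(s) (%s of %d permutations)\n",
              x$n_factors, x$summary, x$n_permutations))
  invisible(x)
}

#' Regression-method factor scores
#'
#' Thurstone regression scores: z-scored data multiplied by R^-1 Lambda,
#' re-standardized to unit variance.
#'
#' @param solution A `factor_solution`.
#' @param data Subjects x measures data in the same column order as the
#'   correlation matrix the solution was fitted to.
#' @return Matrix of per-subject factor scores (one column per factor).
#' @export
factor_scores <- function(solution, data) {
  x <- score_matrix(data)
  if (ncol(x) != nrow(solution$loadings)) {
    stopf("data has %d measures but the solution was fitted to %d",
          ncol(x), nrow(solution$loadings))
  }
  if (any(!complete.cases(x))) stopf("factor scores require complete data")
  z <- scale(x)
  W <- tryCatch(solve(solution$corr, solution$loadings),
                error = function(e) stopf("correlation matrix is singular"))
  s <- z %*% W
  s <- apply(s, 2, zscore_vec)
  colnames(s) <- colnames(solution$loadings) %||% sprintf("F%d", seq_len(ncol(s)))
  rownames(s) <- rownames(x)
  s
}

#' Bootstrap confidence intervals for factor loadings
#'
#' Resamples subjects with replacement, refits the maximum-likelihood
#' factor model on each resample's correlation matrix, sign-aligns each
#' factor, and returns percentile bounds per loading. Resamples where the
#' optimizer fails are dropped (counted in the result).
#'
#' @param data Subjects x measures data.
#' @param n_factors Number of factors.
#' @param n_boot Number of resamples (default 10000).
#' @param probs Percentile bounds (default 5% and 95%).
#' @param seed Integer seed.
#' @return List with `lower`, `upper` (measures x factors matrices),
#'   `probs`, and `n_ok` successful resamples.
#' @export
efa_loading_ci <- function(data, n_factors, n_boot = 10000,
                           probs = c(0.05, 0.95), seed = NULL) {
  x <- score_matrix(data)
  n <- nrow(x); p <- ncol(x)
  with_rng_seed(seed, {
    draws <- array(NA_real_, c(n_boot, p, n_factors))
    ok <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      xb <- x[sample.int(n, replace = TRUE), , drop = FALSE]
      Rb <- tryCatch(cor(xb), error = function(e) NULL)
      if (is.null(Rb) || any(!is.finite(Rb))) next
      fb <- tryCatch(factanal(covmat = Rb, factors = n_factors, rotation = "none"),
                     error = function(e) NULL)
      if (is.null(fb)) next
      draws[b, , ] <- orient_loadings(unclass(fb$loadings)[, , drop = FALSE])
      ok[b] <- TRUE
    }
    if (!any(ok)) stopf("no bootstrap resample converged")
    lower <- apply(draws[ok, , , drop = FALSE], c(2, 3), quantile,
                   probs = probs[1], names = FALSE)
    upper <- apply(draws[ok, , , drop = FALSE], c(2, 3), quantile,
                   probs = probs[2], names = FALSE)
    dimnames(lower) <- dimnames(upper) <- list(colnames(x), NULL)
    list(lower = lower, upper = upper, probs = probs, n_ok = sum(ok))
  })
}

#' Residualize factor scores for age and sex
#'
#' Ordinary least squares of the score on an intercept, age, age squared
#' and sex; the residuals are re-standardized to unit variance. Constant
#' covariate columns are dropped with a warning.
#'
#' @param scores Numeric vector of per-subject factor scores.
#' @param age Age in years.
#' @param sex 0/1 coded sex.
#' @return A numeric vector of standardized residuals with attribute
#'   `dropped` naming any removed covariates.
#' @export
residualize <- function(scores, age, sex) {
  if (any(is.na(scores)) || any(is.na(age)) || any(is.na(sex))) {
    stopf("residualize requires complete scores and covariates")
  }
  covars <- list(age = age, age2 = age^2, sex = sex)
  keep <- vapply(covars, function(v) stats::sd(v) > 0, logical(1))
  if (!all(keep)) {
    warnf("dropping constant covariate(s): %s", paste(names(covars)[!keep], collapse = ", "))
  }
  covars <- covars[keep]
  r <- if (length(covars) == 0) scores - mean(scores) else {
    resid(lm(scores ~ ., data = as.data.frame(covars)))
  }
  # scores fully explained by the covariates: nothing left to standardize
  if (stats::sd(r) < 1e-10 * max(stats::sd(scores), 1)) {
    out <- as.numeric(r)
    attr(out, "dropped") <- names(keep)[!keep]
    return(out)
  }
  out <- zscore_vec(r)
  attr(out, "dropped") <- names(keep)[!keep]
  out
}
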