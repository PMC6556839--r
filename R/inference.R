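#' One-sample t statistic against a reference mean of zero
#'
#' Used to test whether age-normed scores depart from the normative
#' expectation (mean 0): `t = mean / (sd / sqrt(n))` with a two-sided p
#' from Student's t with n-1 degrees of freedom.
#'
#' @param mean Sample mean of the normed scores.
#' @param sd Sample standard deviation (> 0).
#' @param n Sample size (>= 2).
#' @return List with `t`, `df`, `p`.
#' @examples
#' one_sample_t(-1.17, 0.886, 139)$t  # about -15.57
#' @export
one_sample_t <- function(mean, sd, n) {
  if (sd <= 0) stopf("sd must be positive")
  if (n < 2) stopf("n must be >= 2")
  t <- mean / (sd / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

#' Simple regression on standardized variables
#'
#' z-scores both variables, so the slope is the Pearson correlation and a
#' standardized beta; reports R^2 = beta^2, the F statistic
#' `R2 * df2 / (1 - R2)` with (1, n-2) df, its p-value, and a 5-95%
#' bootstrap confidence band for the fitted line obtained by resampling
#' subjects.
#'
#' @param x,y Finite numeric vectors of equal length (n >= 3).
#' @param n_boot Bootstrap resamples for the confidence band (default 500).
#' @param seed Integer seed for the bootstrap.
#' @param grid_size Number of x positions at which the band is evaluated.
#' @return A `regression_result`: `beta`, `R2`, `F`, `df`, `p`, and `band`
#'   (data frame: x, lower, upper) when `n_boot > 0`.
#' @export
simple_regression_standardized <- function(x, y, n_boot = 500, seed = NULL,
                                           grid_size = 25) {
  if (length(x) != length(y)) stopf("x and y must have the same length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("x and y must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("x and y must have positive variance")
  zx <- zscore_vec(x); zy <- zscore_vec(y)
  beta <- cor(zx, zy)
  R2 <- beta^2
  df <- c(1, n - 2)
  Fstat <- R2 * df[2] / (1 - R2)
  p <- pf(Fstat, df[1], df[2], lower.tail = FALSE)
  band <- NULL
  if (n_boot > 0) {
    grid <- seq(min(zx), max(zx), length.out = grid_size)
    fits <- with_rng_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, replace = TRUE)
        xb <- zx[i]; yb <- zy[i]
        slope <- cov(xb, yb) / var(xb)
        mean(yb) + slope * (grid - mean(xb))
      }, numeric(grid_size))
    })
    band <- data.frame(x = grid,
                       lower = apply(fits, 1, quantile, probs = 0.05, names = FALSE),
                       upper = apply(fits, 1, quantile, probs = 0.95, names = FALSE))
  }
  structure(list(beta = beta, R2 = R2, F = Fstat, df = df, p = p, band = band,
                 n = n), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("beta = %.3f, R2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              x$beta, x$R2, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

# Standardized mediation paths from correlations: a = r_xm;
# b, c' are the partial slopes of y on (m, x) for standardized variables.
paths_from_cor <- function(r_xm, r_xy, r_my) {
  denom <- 1 - r_xm^2
  list(a = r_xm,
       b = (r_my - r_xy * r_xm) / denom,
       c_prime = (r_xy - r_my * r_xm) / denom,
       c = r_xy)
}

#' Mediation of a predictor's effect through an intermediate variable
#'
#' Product-of-coefficients mediation with standardized variables: the path
#' a is the slope of m on x, the paths b and c' come from the joint
#' regression of y on x and m, and the total effect c from y on x, so that
#' `c = c' + a*b` exactly. The indirect effect a*b gets a percentile
#' bootstrap confidence interval over subject resamples; partial mediation
#' is flagged when that interval excludes zero while the direct path c'
#' remains significant.
#'
#' @param x Predictor (e.g. global-efficiency AUC).
#' @param m Mediator (e.g. cognitive factor score).
#' @param y Outcome (e.g. attainment factor score).
#' @param n_boot Bootstrap resamples for the indirect-effect CI
#'   (default 5000; 0 skips the interval and reports point estimates only).
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval
#'   (default 0.95).
#' @return A `mediation_result`: paths `a`, `b`, `c`, `c_prime`, `indirect`,
#'   `indirect_ci`, `proportion_mediated`, `partial_mediation`, and the
#'   direct-path p-value `p_c_prime`.
#' @export
mediation <- function(x, m, y, n_boot = 5000, seed = NULL, conf_level = 0.95) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stopf("x, m, y must be aligned vectors")
  if (n < 10) stopf("mediation needs at least 10 complete triples")
  if (any(!complete.cases(cbind(x, m, y)))) stopf("x, m, y must be complete")
  zx <- zscore_vec(x); zm <- zscore_vec(m); zy <- zscore_vec(y)
  r_xm <- cor(zx, zm)
  if (abs(r_xm) > 0.999) stopf("x and m are collinear (|r| = %.4f)", abs(r_xm))
  pth <- paths_from_cor(r_xm, cor(zx, zy), cor(zm, zy))
  fit_ym <- lm(zy ~ zx + zm)
  p_c_prime <- summary(fit_ym)$coefficients["zx", 4]
  alpha <- (1 - conf_level) / 2
  ci <- if (n_boot == 0) c(NA_real_, NA_real_) else with_rng_seed(seed, {
    ind <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      R <- cor(cbind(zx[i], zm[i], zy[i]))
      pb <- paths_from_cor(R[1, 2], R[1, 3], R[2, 3])
      pb$a * pb$b
    }, numeric(1))
    quantile(ind, probs = c(alpha, 1 - alpha), names = FALSE)
  })
  indirect <- pth$a * pth$b
  structure(list(a = pth$a, b = pth$b, c = pth$c, c_prime = pth$c_prime,
                 indirect = indirect, indirect_ci = ci,
                 proportion_mediated = indirect / pth$c,
                 p_c_prime = p_c_prime,
                 partial_mediation = if (n_boot == 0) NA else {
                   (ci[1] > 0 || ci[2] < 0) && p_c_prime < 0.05
                 },
                 n = n, n_boot = n_boot, conf_level = conf_level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (n = %d): a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$n, x$a, x$b, x$c, x$c_prime))
  cat(sprintf("indirect a*b = %.3f, %.0f%% CI [%.3f, %.3f], proportion mediated %.2f\n",
              x$indirect, 100 * x$conf_level, x$indirect_ci[1], x$indirect_ci[2],
              x$proportion_mediated))
  invisible(x)
}

#' Regional associations between nodal efficiency and factor scores
#'
#' Per region, the standardized slope of the factor score on that region's
#' nodal-efficiency AUC, without and (when per-region grey-matter volumes
#' are supplied) with the region's volume as a covariate — larger regions
#' intersect more streamlines, so volume is a plausible confound. A
#' constant volume column is dropped with a warning, leaving the corrected
#' map equal to the uncorrected one for that region.
#'
#' @param ej_auc Subjects x nodes matrix of nodal-efficiency AUC values.
#' @param factor_scores Numeric vector of per-subject factor scores.
#' @param volumes Optional subjects x nodes matrix of grey-matter volumes.
#' @param p_adjust Multiple-testing adjustment across nodes passed to
#'   [stats::p.adjust] (default `"none"`, descriptive maps; `"BH"`
#'   available).
#' @return A data frame with one row per node: `node`, `beta`, `p`, and
#'   `beta_vol`, `p_vol` when volumes are given.
#' @export
regional_association <- function(ej_auc, factor_scores, volumes = NULL,
                                 p_adjust = "none") {
  ej_auc <- as.matrix(ej_auc)
  n <- nrow(ej_auc); p <- ncol(ej_auc)
  if (length(factor_scores) != n) stopf("factor_scores must have one value per subject")
  if (!is.null(volumes)) {
    volumes <- as.matrix(volumes)
    if (!identical(dim(volumes), dim(ej_auc))) {
      stopf("volumes is %d x %d but ej_auc is %d x %d",
            nrow(volumes), ncol(volumes), n, p)
    }
  }
  zs <- zscore_vec(factor_scores)
  nodes <- colnames(ej_auc) %||% sprintf("roi_%03d", seq_len(p))
  beta <- pv <- beta_vol <- pv_vol <- rep(NA_real_, p)
  dropped_any <- FALSE
  for (j in seq_len(p)) {
    ze <- zscore_vec(ej_auc[, j])
    fit <- summary(lm(zs ~ ze))$coefficients
    beta[j] <- fit["ze", 1]; pv[j] <- fit["ze", 4]
    if (!is.null(volumes)) {
      if (stats::sd(volumes[, j]) == 0) {
        dropped_any <- TRUE
        beta_vol[j] <- beta[j]; pv_vol[j] <- pv[j]
      } else {
        zv <- zscore_vec(volumes[, j])
        fv <- summary(lm(zs ~ ze + zv))$coefficients
        beta_vol[j] <- fv["ze", 1]; pv_vol[j] <- fv["ze", 4]
      }
    }
  }
  if (dropped_any) warnf("constant volume column(s) dropped from the corrected map")
  pv <- stats::p.adjust(pv, method = p_adjust)
  out <- data.frame(node = nodes, beta = beta, p = pv, stringsAsFactors = FALSE)
  if (!is.null(volumes)) {
    out$beta_vol <- beta_vol
    out$p_vol <- stats::p.adjust(pv_vol, method = p_adjust)
  }
  out
}

#' Simple regressions of outcomes on nuisance variables
#'
#' One standardized simple regression per outcome x nuisance pair
#' (age, age squared, sex, motion, brain volume, ...), reported as a tidy
#' table of standardized betas and p-values — the screen for confounding of
#' the factor scores and the efficiency AUC.
#'
#' @param outcomes Data frame or matrix of outcome columns.
#' @param nuisance_table Data frame or matrix of nuisance columns.
#' @return Data frame with columns `outcome`, `nuisance`, `beta`, `p`.
#' @export
nuisance_regressions <- function(outcomes, nuisance_table) {
  yo <- score_matrix(outcomes)
  xn <- score_matrix(nuisance_table)
  if (nrow(yo) != nrow(xn)) stopf("outcomes and nuisance tables must be aligned")
  grid <- expand.grid(outcome = colnames(yo), nuisance = colnames(xn),
                      stringsAsFactors = FALSE)
  res <- t(mapply(function(o, v) {
    r <- simple_regression_standardized(xn[, v], yo[, o], n_boot = 0)
    c(beta = r$beta, p = r$p)
  }, grid$outcome, grid$nuisance))
  cbind(grid, as.data.frame(res))
}
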