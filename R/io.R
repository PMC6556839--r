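#' Read a connectivity matrix from square CSV
#'
#' Expects a numeric square matrix with a header row and a first column of
#' region labels that match the header. Asymmetric input (within numeric
#' noise) is symmetrised by averaging with a warning; negative entries are
#' rejected.
#'
#' @param path CSV file path.
#' @return A [weighted_network].
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stopf("%s: matrix is %d x %d, expected square", path, nrow(m), ncol(m))
  }
  if (!identical(labels, colnames(m))) {
    stopf("%s: row labels do not match column header", path)
  }
  if (!is.numeric(m) || any(!is.finite(m))) {
    stopf("%s: matrix must be fully numeric and finite", path)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stopf("%s: negative weight at row %s, column %s", path,
          labels[bad[1]], labels[bad[2]])
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    warnf("%s: asymmetric by up to %.3g; symmetrised by averaging", path, asym)
    m <- (m + t(m)) / 2
  }
  diag(m) <- 0
  weighted_network(m, labels = labels)
}

#' Write a network as square CSV
#'
#' @param net A [weighted_network].
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(net, path) {
  df <- data.frame(region = net$labels, net$weights, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' A single serializable document holding everything a run needs, so a
#' published run can be reproduced from its config and seed alone. Every
#' stochastic stage draws from a sub-seed derived deterministically from
#' the top-level seed.
#'
#' @param n_subjects Cohort size when simulating.
#' @param seed Top-level integer seed.
#' @param cohort Named list of [cohort_spec] overrides (n_nodes, paths,
#'   loadings, ...).
#' @param densities Proportional-threshold grid.
#' @param length_map `"inverse"` or `"neglog"`.
#' @param efa List: `n_permutations` for parallel analysis, `null_summary`
#'   (`"mean"`/`"p95"`), `n_boot` for loading CIs.
#' @param mediation_n_boot Bootstrap resamples for the indirect-effect CI.
#' @param input Optional list with `manifest`, `scores`, `nuisance` CSV
#'   paths; when present the pipeline reads data instead of simulating.
#' @param out Optional output directory; when given, all intermediate
#'   artifacts and the report are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 139, seed = 1L, cohort = list(),
                       densities = default_densities(),
                       length_map = "inverse",
                       efa = list(n_permutations = 1000, null_summary = "mean",
                                  n_boot = 0),
                       mediation_n_boot = 5000,
                       input = NULL, out = NULL) {
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 cohort = cohort, densities = densities,
                 length_map = length_map, efa = efa,
                 mediation_n_boot = mediation_n_boot,
                 input = input, out = out),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' The JSON round-trip is the identity on the config contents.
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  cfg[names(raw)] <- raw
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (simulation by default, CSV input
#' when configured), per-subject efficiency profiles with AUC aggregation,
#' score normalization and outlier screening, parallel analysis and
#' maximum-likelihood factor analysis for the cognitive and attainment
#' batteries, factor scoring and age/sex residualization, nuisance
#' regressions, the three standardized simple regressions (efficiency ->
#' cognition, efficiency -> attainment, cognition -> attainment), the
#' bootstrap mediation model, and the regional nodal-efficiency association
#' maps with grey-matter-volume correction. Identical config and seed give
#' identical numeric output.
#'
#' @param config A [run_config].
#' @return A `pipeline_report` list with all stage results; written to
#'   `config$out` (JSON + CSVs) when an output directory is configured.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  cohort <- stage("cohort", {
    if (!is.null(config$input)) {
      load_cohort_csv(config$input)
    } else {
      spec <- do.call(cohort_spec, modifyList(
        list(n_subjects = config$n_subjects, seed = derive_seed(config$seed, 10L),
             densities = config$densities),
        config$cohort))
      sample_cohort(spec)
    }
  })
  tick("cohort")

  eff <- stage("efficiency", {
    efficiency_batch(cohort$connectomes, densities = config$densities,
                     length_map = config$length_map)
  })
  tick("efficiency")

  cog_cols <- grep("^cog_", names(cohort$scores), value = TRUE)
  att_cols <- grep("^att_", names(cohort$scores), value = TRUE)
  if (length(config$densities) < 2) stopf("AUC aggregation needs >= 2 densities")

  psych <- stage("psychometrics", {
    z_cog <- zscore(cohort$scores[cog_cols])
    z_att <- zscore(cohort$scores[att_cols])
    screen <- list(cognitive = screen_outliers(z_cog),
                   attainment = screen_outliers(z_att))
    pa_cog <- parallel_analysis(z_cog, n_permutations = config$efa$n_permutations,
                                seed = derive_seed(config$seed, 21L),
                                summary = config$efa$null_summary)
    pa_att <- parallel_analysis(z_att, n_permutations = config$efa$n_permutations,
                                seed = derive_seed(config$seed, 22L),
                                summary = config$efa$null_summary)
    n <- nrow(z_cog)
    efa_cog <- ml_efa(cor(score_matrix(z_cog)), max(1L, pa_cog$n_factors), n,
                      data = z_cog, n_boot = config$efa$n_boot,
                      seed = derive_seed(config$seed, 23L))
    efa_att <- ml_efa(cor(score_matrix(z_att)), max(1L, pa_att$n_factors), n,
                      data = z_att, n_boot = config$efa$n_boot,
                      seed = derive_seed(config$seed, 24L))
    list(screen = screen, pa_cog = pa_cog, pa_att = pa_att,
         efa_cog = efa_cog, efa_att = efa_att)
  })
  tick("psychometrics")

  scores <- stage("residualize", {
    nuis <- cohort$nuisance
    list(cog = residualize(psych$efa_cog$scores[, 1], nuis$age, nuis$sex),
         att = residualize(psych$efa_att$scores[, 1], nuis$age, nuis$sex))
  })
  tick("residualize")

  infer <- stage("inference", {
    eg <- eff$auc_global
    nuis_cols <- intersect(c("age", "age2", "sex", "motion", "brain_vol"),
                           names(cohort$nuisance))
    nuis_tab <- nuisance_regressions(
      data.frame(cognitive = scores$cog, attainment = scores$att, E_G = eg),
      cohort$nuisance[nuis_cols])
    reg <- list(
      eg_cog = simple_regression_standardized(eg, scores$cog, n_boot = 500,
                                              seed = derive_seed(config$seed, 31L)),
      eg_att = simple_regression_standardized(eg, scores$att, n_boot = 500,
                                              seed = derive_seed(config$seed, 32L)),
      cog_att = simple_regression_standardized(scores$cog, scores$att, n_boot = 500,
                                               seed = derive_seed(config$seed, 33L)))
    med <- mediation(eg, scores$cog, scores$att,
                     n_boot = config$mediation_n_boot,
                     seed = derive_seed(config$seed, 34L))
    gmv_cols <- grep("^gmv_", names(cohort$nuisance), value = TRUE)
    vols <- if (length(gmv_cols)) as.matrix(cohort$nuisance[gmv_cols]) else NULL
    maps <- list(
      cognitive = regional_association(eff$auc_nodal, scores$cog, vols),
      attainment = regional_association(eff$auc_nodal, scores$att, vols))
    list(nuisance = nuis_tab, regressions = reg, mediation = med, maps = maps)
  })
  tick("inference")

  report <- structure(list(
    config = config,
    n_subjects = length(eff$auc_global),
    retained_factors = list(cognitive = psych$pa_cog$n_factors,
                            attainment = psych$pa_att$n_factors),
    efa = list(cognitive = psych$efa_cog, attainment = psych$efa_att),
    outlier_screen = psych$screen,
    eg_auc = eff$auc_global,
    ej_auc = eff$auc_nodal,
    factor_scores = scores,
    nuisance = infer$nuisance,
    regressions = infer$regressions,
    mediation = infer$mediation,
    regional_maps = infer$maps,
    timings = timings
  ), class = "pipeline_report")
  if (!is.null(config$out)) write_report(report, config$out)
  report
}

load_cohort_csv <- function(input) {
  manifest <- read.csv(input$manifest, stringsAsFactors = FALSE)
  nets <- lapply(manifest$path, read_matrix_csv)
  names(nets) <- manifest$subject
  scores <- read.csv(input$scores, stringsAsFactors = FALSE)
  nuisance <- if (!is.null(input$nuisance)) {
    read.csv(input$nuisance, stringsAsFactors = FALSE)
  } else NULL
  list(connectomes = nets, scores = scores, nuisance = nuisance)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report: %d subjects\n", x$n_subjects))
  cat(sprintf("retained factors: cognitive %d, attainment %d\n",
              x$retained_factors$cognitive, x$retained_factors$attainment))
  r <- x$regressions
  cat(sprintf("E_G -> cognition:  beta = %.3f, R2 = %.3f\n", r$eg_cog$beta, r$eg_cog$R2))
  cat(sprintf("E_G -> attainment: beta = %.3f, R2 = %.3f\n", r$eg_att$beta, r$eg_att$R2))
  cat(sprintf("cognition -> attainment: beta = %.3f, R2 = %.3f\n",
              r$cog_att$beta, r$cog_att$R2))
  print(x$mediation)
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ej <- report$ej_auc
  tidy <- data.frame(subject = rep(rownames(ej), times = ncol(ej)),
                     node = rep(colnames(ej), each = nrow(ej)),
                     ej_auc = as.vector(ej))
  write.csv(tidy, file.path(dir, "ej_auc.csv"), row.names = FALSE)
  write.csv(data.frame(subject = names(report$eg_auc),
                       eg_auc = report$eg_auc,
                       cog_factor = report$factor_scores$cog,
                       att_factor = report$factor_scores$att),
            file.path(dir, "subject_summary.csv"), row.names = FALSE)
  write.csv(report$nuisance, file.path(dir, "nuisance_regressions.csv"),
            row.names = FALSE)
  write.csv(report$regional_maps$cognitive,
            file.path(dir, "regional_map_cognitive.csv"), row.names = FALSE)
  write.csv(report$regional_maps$attainment,
            file.path(dir, "regional_map_attainment.csv"), row.names = FALSE)
  med <- report$mediation
  reg <- report$regressions
  jsonlite::write_json(list(
    seed = report$config$seed,
    n_subjects = report$n_subjects,
    retained_factors = report$retained_factors,
    efa = list(
      cognitive = list(loadings = as.vector(report$efa$cognitive$loadings),
                       var_explained = report$efa$cognitive$var_explained,
                       fit = report$efa$cognitive$fit),
      attainment = list(loadings = as.vector(report$efa$attainment$loadings),
                        var_explained = report$efa$attainment$var_explained,
                        fit = report$efa$attainment$fit)),
    regressions = lapply(reg, function(r) list(beta = r$beta, R2 = r$R2,
                                               F = r$F, p = r$p)),
    mediation = list(a = med$a, b = med$b, c = med$c, c_prime = med$c_prime,
                     indirect = med$indirect, indirect_ci = med$indirect_ci,
                     proportion_mediated = med$proportion_mediated,
                     partial_mediation = med$partial_mediation)
  ), file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  txt <- file.path(dir, "report.txt")
  sink(txt); on.exit(sink())
  print(report)
  invisible(dir)
}
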