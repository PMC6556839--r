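#' Specification of a synthetic cohort
#'
#' Bundles and validates the generating parameters of a synthetic study
#' cohort: an FA-weighted template connectome, a subject-level white-matter
#' integrity gradient that couples connectome weights (and hence global
#' efficiency) to a latent trait, a one-factor model for observed cognitive
#' scores loading on latent general ability g, a one-factor model for
#' attainment scores, and the standardized causal paths
#' efficiency -> g (`path_a`), g -> attainment (`path_b`) and the direct
#' efficiency -> attainment path (`path_cprime`).
#'
#' Defaults mirror a two-sample child study: 85 regions (68 cortical + 17
#' subcortical), cognitive loadings (0.75, 0.62, 0.66, 0.82, 0.59),
#' attainment loadings (0.93, 0.91, 0.74), and paths (0.345, 0.55, 0.19).
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_nodes Number of network regions (>= 3); default 85.
#' @param template_density Fraction of possible edges present in the raw
#'   template connectome, in (0, 1]; default 0.6.
#' @param integrity_effect Gamma, the strength with which the latent
#'   integrity trait scales subject connectome weights; 0 decouples them.
#' @param path_a,path_b,path_cprime Standardized structural paths; the
#'   implied variance `b^2 + c'^2 + 2*a*b*c'` of the attainment latent must
#'   not exceed 1 and `|a| <= 1`.
#' @param cognitive_loadings,attainment_loadings Standardized loadings in
#'   (0, 1) of the observed scores on their latent factor.
#' @param noise_sd SD of the edge-level perturbation inside the logistic
#'   weight model.
#' @param densities Density grid used when computing each subject's global
#'   efficiency AUC.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects,
                        n_nodes = 85,
                        template_density = 0.6,
                        integrity_effect = 1,
                        path_a = 0.345,
                        path_b = 0.55,
                        path_cprime = 0.19,
                        cognitive_loadings = c(0.75, 0.62, 0.66, 0.82, 0.59),
                        attainment_loadings = c(0.93, 0.91, 0.74),
                        noise_sd = 0.5,
                        densities = default_densities(),
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects), n_nodes = as.integer(n_nodes),
               template_density = template_density,
               integrity_effect = integrity_effect,
               path_a = path_a, path_b = path_b, path_cprime = path_cprime,
               cognitive_loadings = cognitive_loadings,
               attainment_loadings = attainment_loadings,
               noise_sd = noise_sd, densities = densities,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (spec$n_subjects < 3) stopf("n_subjects must be >= 3")
  if (spec$n_nodes < 3) stopf("n_nodes must be >= 3")
  if (spec$template_density <= 0 || spec$template_density > 1) {
    stopf("template_density must be in (0, 1]")
  }
  lam <- c(spec$cognitive_loadings, spec$attainment_loadings)
  if (any(lam <= 0 | lam >= 1)) stopf("all loadings must lie strictly in (0, 1)")
  if (spec$path_a^2 > 1) stopf("path_a^2 exceeds 1: the latent g variance is negative")
  v <- spec$path_b^2 + spec$path_cprime^2 +
    2 * spec$path_a * spec$path_b * spec$path_cprime
  if (v > 1) {
    stopf("paths imply attainment variance %.3f > 1; shrink path_b/path_cprime", v)
  }
  if (spec$noise_sd <= 0) stopf("noise_sd must be positive")
  invisible(spec)
}

#' Generate a template FA-weighted connectome
#'
#' Stand-in for a group-average connectome: nodes get random spatial
#' coordinates in the unit cube, edges are drawn with distance-dependent
#' probability (short-range connections are more likely, as in real brain
#' networks), weights are beta-distributed in (0, 1) to mimic FA, and
#' connectivity is guaranteed by adding the edges of a Euclidean minimum
#' spanning tree when the random draw leaves the graph disconnected.
#'
#' @param n_nodes Number of regions (>= 3).
#' @param template_density Fraction of possible edges, in (0, 1].
#' @param seed Integer seed.
#' @return A connected [weighted_network] with `round(density * n(n-1)/2)`
#'   edges, or slightly more after spanning-tree repair.
#' @export
make_template_network <- function(n_nodes, template_density, seed = 1L) {
  if (n_nodes < 3) stopf("n_nodes must be >= 3")
  if (template_density <= 0 || template_density > 1) {
    stopf("template_density must be in (0, 1]")
  }
  with_rng_seed(seed, {
    xyz <- matrix(runif(3 * n_nodes), ncol = 3)
    d <- as.matrix(stats::dist(xyz))
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    n_pairs <- nrow(pairs)
    k <- round(template_density * n_pairs)
    # distance-dependent edge selection: probability decays with separation
    p <- exp(-d[pairs] / 0.35)
    pick <- if (k >= n_pairs) seq_len(n_pairs) else {
      sample.int(n_pairs, k, prob = p)
    }
    w <- matrix(0, n_nodes, n_nodes)
    sel <- pairs[pick, , drop = FALSE]
    w[sel] <- rbeta(nrow(sel), 5, 5)
    w <- w + t(w)
    net <- weighted_network(w)
    g <- igraph::graph_from_adjacency_matrix(net$weights > 0, mode = "undirected")
    if (!igraph::is_connected(g)) {
      # connect via the Euclidean MST: add its missing edges with fresh weights
      gd <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
      mst <- igraph::mst(gd)
      me <- igraph::as_edgelist(mst, names = FALSE)
      for (r in seq_len(nrow(me))) {
        i <- me[r, 1]; j <- me[r, 2]
        if (net$weights[i, j] == 0) {
          wij <- rbeta(1, 5, 5)
          net$weights[i, j] <- net$weights[j, i] <- wij
        }
      }
    }
    net
  })
}

#' Sample a synthetic cohort
#'
#' Generates, per subject i: a latent white-matter integrity trait
#' `s_i ~ N(0,1)`; a subject connectome whose edge weights are the template
#' weights scaled by `logistic(gamma * s_i + eps_uv)` (weights stay in
#' (0, 1), and global efficiency increases monotonically in `s_i` when
#' `gamma > 0`); the subject's global-efficiency AUC across the density
#' grid, z-scored over the cohort; latent general ability
#' `g_i = a * z(EG_i) + sqrt(1 - a^2) * e_i`; a latent attainment trait
#' `y_i = b * g_i + c' * z(EG_i) + residual` with the residual scaled so
#' `var(y) = 1`; observed cognitive and attainment scores from one-factor
#' models `x_ij = lambda_j * latent + sqrt(1 - lambda_j^2) * noise`; and
#' independent nuisance variables (age uniform 7-12 y, sex Bernoulli(0.5),
#' head motion lognormal in mm, total brain and per-region grey-matter
#' volumes normal in mm^3).
#'
#' @param spec A [cohort_spec].
#' @return A `synthetic_cohort`: list with `connectomes` (list of
#'   [weighted_network]), `scores` (data frame: subject id, cognitive
#'   `cog_*` and attainment `att_*` columns), `nuisance` (data frame: age,
#'   age2, sex, motion, brain_vol and per-region `gmv_*` columns),
#'   `efficiency` (global AUC vector and subjects x nodes nodal AUC matrix,
#'   as computed by the analysis route), and `truth` (generating latents;
#'   for recovery tests only, never consumed by analysis stages).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec") || is.list(spec))
  validate_cohort_spec(spec)
  n <- spec$n_subjects
  template <- make_template_network(spec$n_nodes, spec$template_density,
                                    seed = derive_seed(spec$seed, 1L))
  with_rng_seed(derive_seed(spec$seed, 2L), {
    ids <- sprintf("sub_%04d", seq_len(n))
    s <- rnorm(n)
    tw <- template$weights
    edge_idx <- which(upper.tri(tw) & tw > 0)
    n_edges <- length(edge_idx)
    connectomes <- vector("list", n)
    for (i in seq_len(n)) {
      mult <- stats::plogis(spec$integrity_effect * s[i] +
                              rnorm(n_edges, sd = spec$noise_sd))
      w <- matrix(0, spec$n_nodes, spec$n_nodes)
      w[edge_idx] <- pmin(pmax(tw[edge_idx] * mult, 1e-6), 1 - 1e-6)
      w <- w + t(w)
      connectomes[[i]] <- weighted_network(w, labels = template$labels)
    }
    names(connectomes) <- ids

    eff <- efficiency_batch(connectomes, densities = spec$densities)
    z_eg <- zscore_vec(eff$auc_global)

    a <- spec$path_a; b <- spec$path_b; cp <- spec$path_cprime
    g <- a * z_eg + sqrt(1 - a^2) * rnorm(n)
    resid_var <- 1 - (b^2 + cp^2 + 2 * a * b * cp)
    y <- b * g + cp * z_eg + sqrt(max(resid_var, 0)) * rnorm(n)

    one_factor_scores <- function(latent, loadings, prefix) {
      out <- sapply(seq_along(loadings), function(j) {
        loadings[j] * latent + sqrt(1 - loadings[j]^2) * rnorm(n)
      })
      colnames(out) <- sprintf("%s_%d", prefix, seq_along(loadings))
      out
    }
    cog <- one_factor_scores(g, spec$cognitive_loadings, "cog")
    att <- one_factor_scores(y, spec$attainment_loadings, "att")
    scores <- data.frame(subject = ids, cog, att, stringsAsFactors = FALSE)

    age <- runif(n, 7, 12)
    gmv <- matrix(rnorm(n * spec$n_nodes, 6000, 800), n, spec$n_nodes,
                  dimnames = list(ids, sprintf("gmv_%s", template$labels)))
    gmv[gmv < 500] <- 500
    nuisance <- data.frame(subject = ids,
                           age = age, age2 = age^2,
                           sex = rbinom(n, 1, 0.5),
                           motion = rlnorm(n, meanlog = log(0.6), sdlog = 0.5),
                           brain_vol = rnorm(n, 1.2e6, 1e5),
                           gmv, stringsAsFactors = FALSE)

    structure(list(
      connectomes = connectomes,
      scores = scores,
      nuisance = nuisance,
      efficiency = list(auc_global = eff$auc_global, auc_nodal = eff$auc_nodal,
                        densities = spec$densities),
      truth = list(s = s, g = g, attainment = y, eg_auc = eff$auc_global,
                   z_eg = z_eg, spec = spec),
      spec = spec
    ), class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d-node connectomes, %d cognitive + %d attainment scores\n",
              x$spec$n_subjects, x$spec$n_nodes,
              length(x$spec$cognitive_loadings), length(x$spec$attainment_loadings)))
  invisible(x)
}

#' Simulate standardized mediation triples
#'
#' Draws (x, m, y) directly from the standardized path model
#' `m = a*x + sqrt(1-a^2)*e`, `y = b*m + c'*x + residual` with all three
#' variables of unit population variance — a lightweight generator for
#' calibrating the mediation estimator when the connectome machinery is not
#' needed.
#'
#' @param n Number of triples.
#' @param a,b,cprime Standardized generating paths.
#' @param seed Integer seed.
#' @return Data frame with columns `x`, `m`, `y`.
#' @export
simulate_path_triples <- function(n, a, b, cprime, seed = NULL) {
  v <- b^2 + cprime^2 + 2 * a * b * cprime
  if (a^2 > 1 || v > 1) stopf("paths imply a variance above 1")
  with_rng_seed(seed, {
    x <- rnorm(n)
    m <- a * x + sqrt(1 - a^2) * rnorm(n)
    y <- b * m + cprime * x + sqrt(1 - v) * rnorm(n)
    data.frame(x = x, m = m, y = y)
  })
}

#' Write a synthetic cohort to disk
#'
#' Per-subject connectomes as square CSV matrices with region-label
#' header/rows, the score and nuisance tables as CSV, and the truth record
#' as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (subject, path).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_dir <- file.path(dir, "connectomes")
  dir.create(mat_dir, showWarnings = FALSE)
  paths <- vapply(names(cohort$connectomes), function(id) {
    p <- file.path(mat_dir, paste0(id, ".csv"))
    write_matrix_csv(cohort$connectomes[[id]], p)
    p
  }, character(1))
  manifest <- data.frame(subject = names(cohort$connectomes), path = paths,
                         stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  write.csv(cohort$nuisance, file.path(dir, "nuisance.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(s = cohort$truth$s, g = cohort$truth$g,
         attainment = cohort$truth$attainment, eg_auc = cohort$truth$eg_auc,
         spec = unclass(cohort$spec)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
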