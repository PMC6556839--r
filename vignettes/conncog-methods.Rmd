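---
title: "Connectome efficiency, psychometric g, and mediation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome efficiency, psychometric g, and mediation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncog)
```

`conncog` implements a pipeline that relates the organisation of a child's
white-matter network to general cognitive ability (g) and educational
attainment: weighted graph efficiency aggregated over proportional density
thresholds, maximum-likelihood factor analysis with parallel analysis, and a
bootstrap mediation model. This vignette explains each model, the tunable
parameters, the synthetic-data generator, and the design decisions taken
where more than one defensible choice existed.

## Network construction and efficiency

The unit of analysis is a `weighted_network`: a symmetric, non-negative,
zero-diagonal matrix of FA (fractional anisotropy) weights over a fixed
parcellation. `build_network()` takes a streamline-count matrix (possibly
asymmetric, because probabilistic tractography is seeded directionally) and
a mean-FA matrix; counts in the two seeding directions are averaged, an edge
exists where the symmetrised count is positive, and the FA value is the edge
weight. FA is dimensionless and lies in [0,1].

Efficiency is computed on edge *lengths* `f(w)`. The weight-to-length map
must be strictly positive and decreasing on (0,1]; the package defaults to
`f(w) = 1/w`, the standard choice for FA-like weights, with `f(w) = -log(w)`
available (`length_map = "neglog"`). The choice matters only up to the
monotone relation between the maps; the inverse map additionally gives an
exact linear scaling law (multiplying all weights by c multiplies E_G by c),
which the test suite exploits as a calibration property.

Nodal efficiency is the per-node mean inverse shortest-path length and
global efficiency is the mean of the nodal values. Two conventions are worth
making explicit:

* **Disconnected pairs** contribute zero inverse distance (1/∞ := 0), the
  standard efficiency convention; no infinities propagate.
* The quantity called nodal efficiency here is the per-node average inverse
  distance to all other nodes. Some of the graph-theory literature uses
  "local efficiency" for a different quantity (efficiency of the
  neighbourhood subgraph). The per-node form is what this pipeline's
  formula states, and it is implemented verbatim; the package deliberately
  does not second-guess it.

Shortest paths are computed by a dense Dijkstra in C++ from every source
(`cpp_apsp`), written for the small, moderately dense matrices typical of
anatomical parcellations. The test suite checks it against an independent
Floyd–Warshall implementation to 1e-12 on hundreds of random graphs.

**Proportional thresholding.** Tractography produces spurious edges, and any
single cleanup cutoff is arbitrary, so metrics are computed across densities
0.30–0.90 and aggregated as the trapezoidal area under the
metric-versus-density curve. The step size within that range is not a
substantive quantity; the package uses 0.05 (13 levels), configurable. At
density d the `round(d·n(n−1)/2)` largest-weight edges are retained; ties at
the boundary are broken by node-pair order (largest weights first), so
thresholding is reproducible even with exactly equal weights. When the
network has fewer nonzero edges than the target, all of them are kept —
edges are never invented.

## Psychometrics

Raw scores are z-scored per measure (sample SD, n−1). Outlier screening
flags (never deletes) subjects with any |z| > 3 and subjects whose squared
Mahalanobis distance exceeds the χ² quantile with df = number of measures.
The tail probability of that cutoff is a convention, not an estimate; the
package uses p = 0.001, configurable.

`ml_efa()` fits the unrotated normal-theory factor model Σ = ΛΛ′ + Ψ by
maximum likelihood via `stats::factanal`, whose lower bound of 0.005 on the
uniquenesses is exactly the Heywood-case clamp this pipeline requires;
measures that hit the bound are reported. Each factor is oriented so its
largest-magnitude loading is positive. Starting values are factanal's
squared-multiple-correlation-based defaults. Fit is summarised by:

* RMSR — root mean square of the off-diagonal residual correlations;
* RMSEA — `sqrt(max(χ²−df, 0)/(df·(n−1)))`;
* Tucker–Lewis index — from the χ²/df ratios of the fitted model and the
  Bartlett-corrected independence model. For a saturated model (df ≤ 0, e.g.
  a one-factor model on three measures) RMSEA and TLI are undefined and
  reported as `NA`.

**Parallel analysis.** Factor retention compares observed eigenvalues of the
correlation matrix (principal components, matching the scree-plot framing)
to eigenvalues of column-permuted data: each permutation shuffles every
column independently, which destroys cross-column structure while preserving
margins. The retained count is the longest leading run of observed
eigenvalues above their null summary. Two conventions are configurable
because the literature states them loosely:

* the null summary — permutation **mean** (default) or 95th percentile.
  Note that with the mean summary, data with *no* structure will still
  retain one factor about half the time (the leading observed eigenvalue is
  drawn from the same distribution as its null); the percentile summary is
  the conservative choice when a zero-factor outcome must be detectable.
* the permutation count — default 10,000 (tests use fewer; the retained
  count stabilises long before that).

**Factor scores** use the regression (Thurstone) method, `R⁻¹Λ` applied to
z-scored data, re-standardized — the default of the psychometric software
family this pipeline mirrors. Bootstrap 5–95% loading intervals resample
subjects (not columns), refit, and sign-align each resample; resamples where
the optimizer fails are dropped and counted.

**Residualization.** Factor scores are residualized on intercept, age, age²
and sex by OLS before any brain–behaviour inference, and re-standardized.
Residuals are exactly orthogonal to the modelled covariates; if the
covariates explain the scores completely the (zero) residuals are returned
unstandardized rather than dividing by a vanishing SD.

## Inference

All regressions are on standardized variables, so slopes are βs and
`R² = β²`, `F = R²·df2/(1−R²)` hold as identities (checked to 1e-8 each
fit). Fitted-line uncertainty uses a 5–95% percentile band over 500 subject
resamples.

Mediation is estimated by two OLS path regressions — `m ~ x` for a, and
`y ~ x + m` for b and c′ — which for a saturated three-variable system is
equivalent to fitting the structural model directly; no latent-variable SEM
is involved. The decomposition `c = c′ + a·b` is then exact on every sample.
The indirect effect's CI is a percentile bootstrap over subject resamples,
5000 by default; 500–1000 give visually identical intervals at n ≈ 100–200
and are used in tests. Partial mediation is flagged when the indirect CI
excludes zero while c′ stays significant.

Regional association maps regress the factor score on each region's nodal
efficiency AUC, with and without that region's grey-matter volume as a
covariate (larger regions intersect more streamlines, a mechanical
confound). No multiple-testing correction is applied by default — the maps
are descriptive — but Benjamini–Hochberg is available via `p_adjust = "BH"`.

## The synthetic-cohort generator

No subject-level imaging data are distributable, so `sample_cohort()`
generates cohorts with the causal and factor structure the analysis assumes:

1. a template connectome (`make_template_network()`): random spatial node
   coordinates, distance-dependent edge probability (short-range connections
   more likely), beta(5,5) FA-like weights, and minimum-spanning-tree repair
   to guarantee connectivity;
2. per subject, a latent integrity trait `s ~ N(0,1)` scales the template
   weights through `logistic(γ·s + ε)`, keeping weights in (0,1) and making
   global efficiency monotone in s — the simplest mechanism that yields a
   continuous efficiency gradient;
3. the subject's z-scored E_G AUC drives latent g (path a), and g plus a
   direct path drive a latent attainment trait (paths b, c′), with residual
   variances chosen so every latent is standardized — the generating paths
   are therefore directly comparable to the fitted standardized βs, and
   specs whose paths would imply variance above 1 are rejected;
4. observed scores load on their latent through one-factor models
   `x_j = λ_j·latent + sqrt(1−λ_j²)·noise`;
5. nuisance variables are independent draws: age uniform 7–12 y, sex
   Bernoulli(0.5), head motion lognormal (median 0.6 mm), total brain volume
   normal (1.2×10⁶ mm³), per-region grey-matter volumes normal (6000 mm³).

Defaults are anchored to the study conditions the pipeline targets: 85
regions (68 Desikan–Killiany cortical + 17 subcortical), densities
0.30–0.90, cognitive loadings (0.75, 0.62, 0.66, 0.82, 0.59), attainment
loadings (0.93, 0.91, 0.74), and paths a = 0.345, b = 0.55, c′ = 0.19 —
the path values are derived from published standardized effect sizes for
the efficiency→cognition, cognition→attainment and efficiency→attainment
relations via the standardized two-regression identities. Two generator
parameters have no empirical anchor and are documented as arbitrary: the
template density (0.6, typical of raw streamline-count connectomes at this
parcellation scale) and the integrity effect γ = 1 with edge noise SD 0.5
(chosen to give a clearly detectable but not degenerate efficiency
gradient).

The cohort carries a `truth` record (the generating latents) for recovery
tests only; no analysis stage reads it, and a test verifies that deleting it
changes nothing.

**What the generator does and does not emulate.** It reproduces the
*statistical* structure the analysis assumes — a one-factor battery, a
standardized path model, an efficiency gradient — but not real anatomy: no
hemispheric organisation, no hub structure, no spatially correlated
grey-matter volumes, no age-related change in the connectome, and nuisance
variables uncoupled from the brain by default. Passing tests therefore
demonstrate that the estimators recover what the model generates, not that
the model describes real developmental data.

## Problem sizes and numerical choices

Simulation-based tests use sizes at which the checked property is stable:
parameter-recovery runs use cohorts of 500–5000 subjects with 12–30-node
networks (the mediation and factor-structure properties do not depend on
node count, and the 85-node default is exercised by the template and
pipeline tests); the mediation point-recovery check averages 20 cohorts of
n = 2000; interval calibration uses 200 replicates at n = 139 with a
1000-resample bootstrap. The acceptance script runs the full pipeline at
n = 139 with the 85-region default.

Other numerical conventions: symmetry of input matrices is required within
1e-8 (and exact symmetry is then restored by averaging); z-scoring rejects
constant columns by name; the mediation estimator rejects predictor–mediator
correlations above 0.999 as collinear; sub-seeds for each pipeline stage are
derived deterministically from the top-level seed, and identical
config + seed reproduce every output byte for byte.

## Known limitations

* The pipeline begins at the matrix level: no tractography, parcellation or
  imaging-format support.
* Only unrotated ML factor solutions: no rotation, confirmatory or
  bifactor models.
* Mediation is cross-sectional OLS with standardized paths; it estimates a
  decomposition, not a causal claim, and no latent-variable measurement
  model is fitted (factor-score attenuation is therefore inherited by the
  paths).
* Regional maps are descriptive by default; the volume correction addresses
  one specific confound only.
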