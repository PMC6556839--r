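# Independent oracles and small fixture builders, kept free of the code
# paths they check.

# Floyd-Warshall all-pairs shortest paths on a dense length matrix
# (vectorised over the intermediate node). Independent of the package's
# Dijkstra implementation.
floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Random symmetric weighted network with approximately the given density.
random_network <- function(n, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  k <- max(1, round(density * length(ut)))
  sel <- sample(ut, k)
  w[sel] <- runif(k, 0.05, 0.95)
  w <- w + t(w)
  weighted_network(w)
}

# Length matrix under the inverse map, for feeding the oracle directly.
inverse_lengths <- function(net) {
  w <- net$weights
  L <- matrix(Inf, nrow(w), ncol(w))
  L[w > 0] <- 1 / w[w > 0]
  diag(L) <- 0
  L
}

# One-factor sample with given standardized loadings.
one_factor_sample <- function(n, loadings, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- rnorm(n)
  sapply(loadings, function(l) l * g + sqrt(1 - l^2) * rnorm(n))
}
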