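#' Construct an FA-weighted brain network
#'
#' A `weighted_network` is the unit of graph analysis: a symmetric,
#' non-negative, zero-diagonal matrix of edge weights (fractional anisotropy,
#' dimensionless, in \[0,1\] for real data) together with ordered region
#' labels. An absent edge is encoded as exactly 0.
#'
#' @param weights Square numeric matrix; symmetric, non-negative, zero
#'   diagonal.
#' @param labels Character vector of region names, one per row. Defaults to
#'   the matrix dimnames or `"roi_001"`, `"roi_002"`, ...
#' @return An object of class `weighted_network` with elements `weights`
#'   (labelled matrix) and `labels`.
#' @examples
#' w <- matrix(c(0, .5, .5, 0), 2, 2)
#' weighted_network(w)
#' @export
weighted_network <- function(weights, labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stopf("weights must be a numeric matrix")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) stopf("weights must be square, got %d x %d", n, ncol(weights))
  if (any(!is.finite(weights))) stopf("weights must be finite")
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-8) {
    stopf("weights must be symmetric (max asymmetry %.3g)", max(abs(weights - t(weights))))
  }
  weights <- (weights + t(weights)) / 2  # remove numerical asymmetry
  diag(weights) <- 0
  if (is.null(labels)) labels <- rownames(weights) %||% sprintf("roi_%03d", seq_len(n))
  if (length(labels) != n) stopf("need %d labels, got %d", n, length(labels))
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = as.character(labels), weights = weights),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- length(x$labels)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("weighted_network: %d nodes, %d edges (density %.3f)\n",
              n, ne, ne / (n * (n - 1) / 2)))
  invisible(x)
}

n_nodes <- function(net) length(net$labels)

edge_density <- function(net) {
  n <- n_nodes(net)
  sum(net$weights[upper.tri(net$weights)] > 0) / (n * (n - 1) / 2)
}

#' Build an FA-weighted network from streamline counts and an FA matrix
#'
#' Mirrors the final step of connectome construction: streamline counts from
#' probabilistic tractography are direction-dependent, so the count matrix is
#' symmetrised by averaging counts in both seeding directions; an edge exists
#' wherever the symmetrised count is positive, and its weight is the mean
#' fractional anisotropy sampled along the connecting streamlines (supplied
#' precomputed in `fa_matrix`).
#'
#' @param count_matrix Square non-negative matrix of streamline counts; may
#'   be asymmetric.
#' @param fa_matrix Square numeric matrix of mean-FA values in \[0,1\], same
#'   shape as `count_matrix`.
#' @param labels Optional region labels.
#' @return A [weighted_network].
#' @examples
#' counts <- matrix(c(0, 4, 2, 0), 2, 2, byrow = TRUE)
#' fa <- matrix(c(0, .5, .5, 0), 2, 2)
#' build_network(counts, fa)
#' @export
build_network <- function(count_matrix, fa_matrix, labels = NULL) {
  if (!is.matrix(count_matrix) || nrow(count_matrix) != ncol(count_matrix)) {
    stopf("count_matrix must be square")
  }
  if (!identical(dim(count_matrix), dim(fa_matrix))) {
    stopf("count_matrix is %d x %d but fa_matrix is %d x %d",
          nrow(count_matrix), ncol(count_matrix), nrow(fa_matrix), ncol(fa_matrix))
  }
  if (any(count_matrix < 0)) stopf("streamline counts must be non-negative")
  if (any(fa_matrix < 0 | fa_matrix > 1)) {
    bad <- which(fa_matrix < 0 | fa_matrix > 1, arr.ind = TRUE)[1, ]
    stopf("FA values must lie in [0,1]; first offender at (%d,%d) = %g",
          bad[1], bad[2], fa_matrix[bad[1], bad[2]])
  }
  cnt <- (count_matrix + t(count_matrix)) / 2
  fa <- (fa_matrix + t(fa_matrix)) / 2
  w <- ifelse(cnt > 0, fa, 0)
  diag(w) <- 0
  weighted_network(w, labels = labels %||% rownames(count_matrix))
}
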