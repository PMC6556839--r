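# Proportional density thresholding.

# Upper-triangle nonzero edges ordered by weight descending, ties broken by
# node-pair lexicographic order so a threshold is reproducible even with
# exactly equal weights at the boundary.
ranked_edges <- function(net) {
  w <- net$weights
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0) return(cbind(i = integer(0), j = integer(0)))
  wt <- w[ut]
  ord <- order(-wt, ut[, 1], ut[, 2])
  ut[ord, , drop = FALSE]
}

# Number of retained edges at a proportional density: round(d * n(n-1)/2),
# capped at the number of nonzero edges actually present.
n_kept_edges <- function(density, n_pairs, n_edges) {
  min(round(density * n_pairs), n_edges)
}

#' Apply a proportional density threshold
#'
#' Retains the `round(density * n(n-1)/2)` largest-weight edges and sets all
#' others to zero; retained weights are unchanged. When fewer nonzero edges
#' exist than the target count, all of them are kept (no edges are ever
#' invented). Ties at the boundary are broken by node-pair order, largest
#' weights first.
#'
#' @param net A [weighted_network].
#' @param density Target edge density in (0, 1].
#' @return A thresholded [weighted_network].
#' @examples
#' w <- matrix(0, 4, 4)
#' w[upper.tri(w)] <- c(.1, .2, .3, .4, .5, .6); w <- w + t(w)
#' proportional_threshold(weighted_network(w), 0.5)  # keeps .6, .5, .4
#' @export
proportional_threshold <- function(net, density) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    stopf("density must be a single value in (0, 1], got %s", format(density))
  }
  n <- n_nodes(net)
  edges <- ranked_edges(net)
  k <- n_kept_edges(density, n * (n - 1) / 2, nrow(edges))
  keep <- head(edges, k)
  w <- matrix(0, n, n, dimnames = dimnames(net$weights))
  if (k > 0) {
    idx <- cbind(keep[, 1], keep[, 2])
    w[idx] <- net$weights[idx]
    w[idx[, 2:1, drop = FALSE]] <- net$weights[idx]
  }
  weighted_network(w, labels = net$labels)
}

#' Threshold a network over a grid of densities
#'
#' @inheritParams proportional_threshold
#' @param densities Strictly increasing densities in (0,1]; default
#'   [default_densities()].
#' @return A `threshold_sweep`: list with `densities` and `networks` (one
#'   thresholded [weighted_network] per density).
#' @export
threshold_sweep <- function(net, densities = default_densities()) {
  if (length(densities) < 1 || any(diff(densities) <= 0)) {
    stopf("densities must be non-empty and strictly increasing")
  }
  nets <- lapply(densities, function(d) proportional_threshold(net, d))
  names(nets) <- sprintf("d%.2f", densities)
  structure(list(densities = densities, networks = nets), class = "threshold_sweep")
}
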