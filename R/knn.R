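# k-nearest-neighbour machinery for baseline support estimation.
#
# For a set of n baseline points the sphere radius of point k is its Euclidean
# distance to the l-th nearest OTHER baseline point, l = max(1, floor(n*gamma)).
# Radii for every candidate l are read off one sorted distance matrix, so a
# gamma search costs a single distance computation per feature (set).

# n x (n-1) matrix: row k holds the sorted distances from point k to the other
# points. `pts` is an n x d matrix (points in rows).
.sorted_neighbor_dists <- function(pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  diag(d) <- Inf
  t(apply(d, 1L, sort))[, seq_len(n - 1L), drop = FALSE]
}

# neighbourhood size for n samples at a given gamma, clamped to >= 1
.knn_l <- function(n, gamma, warn = TRUE) {
  l <- floor(n * gamma)
  if (l < 1L) {
    if (warn)
      warning(sprintf(
        "floor(n * gamma) = 0 for n = %d, gamma = %g; clamping l to 1",
        n, gamma), call. = FALSE)
    l <- 1L
  }
  as.integer(l)
}

# beta trimming: keep spheres with radius <= the beta-quantile of all radii
# (linear interpolation); at least one sphere is always kept.
.kept_spheres <- function(radii, beta) {
  rbar <- stats::quantile(radii, probs = beta, names = FALSE, type = 7)
  kept <- radii <= rbar
  if (!any(kept)) kept[which.min(radii)] <- TRUE
  kept
}
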