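#' Fit the baseline support for a single feature set
#'
#' Low-level entry point exposing the sphere-union support for one
#' multivariate feature: each baseline sample contributes a sphere in
#' `|S|`-dimensional quantile space whose radius is the distance to its
#' `l`-th nearest other baseline sample (`l = max(1, floor(n * gamma))`),
#' and spheres wider than the `beta`-quantile of radii are trimmed.
#' [divfit()] applies this across a whole collection; this function is useful
#' for inspecting a single set's geometry or coding individual points with
#' [code_point()].
#'
#' @inheritParams divfit
#' @param members character vector of feature ids making up the set (all must
#'   be present in `baseline`).
#' @param name optional set name carried in the result.
#' @return a `set_support` object: list with `members`, `centers` (baseline
#'   points in rows), `radii`, `kept` (logical trimming outcome), `gamma`,
#'   `beta` and `l`.
#' @examples
#' base <- matrix(seq(0.1, 1, 0.1), 1, 10,
#'                dimnames = list("g1", paste0("n", 1:10)))
#' s <- fit_support_for_set(base, "g1", gamma = 0.2, beta = 1,
#'                          transformed = TRUE)
#' s$radii  # all 0.2: each point's 2nd-nearest neighbour is 0.2 away
#' @export
fit_support_for_set <- function(baseline, members, gamma, beta = 0.95,
                                transformed = FALSE, name = NULL) {
  baseline <- as_omics_matrix(baseline)
  n <- ncol(baseline)
  if (n < 2L)
    stop("baseline must contain at least 2 samples", call. = FALSE)
  .check_param(gamma, "gamma", 0, 1, TRUE, TRUE)
  .check_param(beta, "beta", 0, 1, lo_open = TRUE)
  members <- as.character(members)
  missing <- setdiff(members, rownames(baseline))
  if (length(missing) > 0L)
    stop(sprintf("set member(s) not in baseline: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  Q <- .as_quantile(baseline, transformed)
  pts <- t(Q[members, , drop = FALSE])
  l <- .knn_l(n, gamma)
  radii <- .sorted_neighbor_dists(pts)[, l]
  kept <- .kept_spheres(radii, beta)
  structure(list(name = name, members = members, centers = pts,
                 radii = radii, kept = kept,
                 gamma = gamma, beta = beta, l = l),
            class = "set_support")
}

#' Binary divergence code of a point against a fitted set support
#'
#' Returns 0 when the point lies inside at least one kept baseline sphere
#' (distance to the sphere's center at most its radius, boundary inclusive)
#' and 1 otherwise, i.e. 1 flags divergence from the baseline.
#'
#' @param support a `set_support` from [fit_support_for_set()], or one element
#'   of a multivariate model's `support` list.
#' @param point numeric vector in quantile space with length equal to the
#'   number of set members.
#' @return integer 0 or 1.
#' @export
code_point <- function(support, point) {
  centers <- support$centers
  if (length(point) != ncol(centers))
    stop(sprintf("point has length %d but the set has %d members",
                 length(point), ncol(centers)), call. = FALSE)
  kept <- which(support$kept)
  d <- sqrt(colSums((t(centers[kept, , drop = FALSE]) - point)^2))
  as.integer(!any(d <= support$radii[kept]))
}
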