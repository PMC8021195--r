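#' Fit a baseline divergence model
#'
#' Estimates the region of quantile space considered "baseline" (non-divergent)
#' from a reference cohort, either per feature (univariate) or per feature set
#' (multivariate). The fitted model is then applied to case samples with
#' [predict.divergence_model()] to obtain the digitized divergence coding.
#'
#' The estimator works in quantile space (see [quantile_transform()]). For each
#' baseline sample the radius of a sphere is its Euclidean distance to the
#' `l`-th nearest other baseline sample, with `l = max(1, floor(n * gamma))`.
#' The support is the union of these spheres after outlier trimming: only
#' spheres with radius at or below the `beta`-quantile of all radii are kept,
#' so roughly a fraction `1 - beta` of the widest spheres is discarded. In the
#' univariate case the union of kept intervals is simplified to a single
#' interval from its lowest to its highest end, clamped to \[0, 1\]; coding
#' against it is ternary (-1 below, +1 above, 0 inside, boundaries inclusive).
#' In the multivariate case a sample is coded 1 for a feature set when its
#' quantile sub-vector lies outside every kept sphere, 0 otherwise.
#'
#' When `gamma` is `NULL` (the default) the neighbourhood size is calibrated:
#' candidates in `gamma_candidates` are evaluated in ascending order and the
#' smallest one whose achieved baseline alpha -- the average proportion of
#' divergent features per baseline sample under the fitted support -- is at or
#' below `alpha` is selected. If no candidate qualifies, the largest candidate
#' is used and a warning is issued; see [select_gamma()].
#'
#' @param baseline numeric feature-by-sample matrix of the reference cohort
#'   (at least 2 samples; at least 20 are recommended for a stable support).
#' @param type `"univariate"` (per-feature intervals, ternary coding) or
#'   `"multivariate"` (per-set sphere unions, binary coding).
#' @param sets named list of character vectors of feature ids (required for
#'   `type = "multivariate"`); members absent from `baseline` are dropped with
#'   a warning and sets left empty are skipped.
#' @param alpha target upper bound for the achieved baseline alpha used by the
#'   gamma search (default 0.01, i.e. at most 1% of features divergent per
#'   baseline sample on average). Ignored when `gamma` is given.
#' @param beta fraction of baseline spheres retained after outlier trimming
#'   (default 0.95). `beta = 1` keeps every sphere, which forces alpha = 0.
#' @param gamma optional fixed neighbourhood-size parameter in (0, 1); when
#'   supplied, no search is performed.
#' @param gamma_candidates ascending candidate list for the gamma search;
#'   defaults to [default_gamma_candidates()].
#' @param transformed set `TRUE` when `baseline` is already on quantile scale;
#'   otherwise [quantile_transform()] is applied internally.
#' @return an object of class `divergence_model` (and `univariate_divergence`
#'   or `multivariate_divergence`), a list with components including
#'   `intervals` (univariate: per-feature lower/upper bounds) or `support`
#'   (multivariate: per-set centers, radii and kept flags), the parameters
#'   `gamma`, `beta`, `l`, `n_baseline`, the `achieved_alpha`, and the gamma
#'   `search` record when a search was run.
#' @seealso [predict.divergence_model()], [select_gamma()], [divergence()]
#' @examples
#' set.seed(1)
#' base <- matrix(rexp(200 * 25), 200, 25,
#'                dimnames = list(paste0("g", 1:200), paste0("n", 1:25)))
#' fit <- divfit(base, beta = 1, gamma = 0.2)
#' fit$achieved_alpha  # 0: with beta = 1 every baseline sample is covered
#' @export
divfit <- function(baseline, type = c("univariate", "multivariate"),
                   sets = NULL, alpha = 0.01, beta = 0.95, gamma = NULL,
                   gamma_candidates = default_gamma_candidates(),
                   transformed = FALSE) {
  type <- match.arg(type)
  cl <- match.call()
  baseline <- as_omics_matrix(baseline)
  n <- ncol(baseline)
  if (n < 2L)
    stop("baseline must contain at least 2 samples", call. = FALSE)
  if (n < 20L)
    warning(sprintf(
      "baseline has only %d samples; at least 20 are recommended", n),
      call. = FALSE)
  .check_param(beta, "beta", lo = 0, hi = 1, lo_open = TRUE)
  Q <- .as_quantile(baseline, transformed)

  if (type == "multivariate") {
    sets <- .resolve_sets(sets, rownames(Q))
    prep <- .prep_multi(Q, sets)
  } else {
    if (!is.null(sets))
      warning("'sets' is ignored for type = \"univariate\"", call. = FALSE)
    prep <- .prep_uni(Q)
  }

  search <- NULL
  if (is.null(gamma)) {
    .check_param(alpha, "alpha", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
    search <- .search_gamma(prep, gamma_candidates, alpha, beta)
    gamma <- search$selected_gamma
    if (!search$converged)
      warning(sprintf(
        "no candidate gamma achieved alpha <= %g; using largest candidate %g",
        alpha, gamma), call. = FALSE)
  } else {
    .check_param(gamma, "gamma", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  }

  l <- .knn_l(n, gamma)
  fit <- if (type == "univariate") .fit_uni(prep, l, beta)
         else .fit_multi(prep, l, beta)
  fit$achieved_alpha <- .alpha_at(prep, l, beta)
  fit$gamma <- gamma
  fit$beta <- beta
  fit$l <- l
  fit$n_baseline <- n
  fit$search <- search
  fit$call <- cl
  class(fit) <- c(paste0(type, "_divergence"), "divergence_model")
  fit
}

#' Default candidate list for the gamma search
#'
#' `0.01, 0.02, ..., 0.09, 0.1, 0.2, ..., 0.9`: a fine grid below 0.1 where
#' the achieved baseline alpha is most sensitive, coarser above.
#'
#' @return ascending numeric vector of 18 candidate values.
#' @export
default_gamma_candidates <- function() {
  c(seq(0.01, 0.09, by = 0.01), seq(0.1, 0.9, by = 0.1))
}

#' Select the smallest gamma meeting an alpha budget
#'
#' Evaluates candidate gamma values in ascending order, fitting the baseline
#' support at each and computing the achieved baseline alpha (average
#' proportion of divergent features per baseline sample, coded in-sample),
#' and returns the first candidate whose alpha is at or below
#' `alpha_threshold`. Since the support grows with gamma, alpha is
#' non-increasing in gamma and the first qualifying candidate is the smallest.
#'
#' @inheritParams divfit
#' @param candidates ascending numeric vector of gamma values in (0, 1).
#' @param alpha_threshold the alpha budget in (0, 1).
#' @return a `gamma_search` object: list with `selected_gamma`,
#'   `candidate_gammas`, `alpha_threshold`, `achieved_alpha_per_candidate`
#'   (named vector over the candidates evaluated before stopping) and
#'   `converged` (`FALSE` when no candidate met the budget, in which case the
#'   largest candidate is reported as selected).
#' @export
select_gamma <- function(baseline, candidates = default_gamma_candidates(),
                         alpha_threshold = 0.01, beta = 0.95, sets = NULL,
                         transformed = FALSE) {
  baseline <- as_omics_matrix(baseline)
  if (ncol(baseline) < 2L)
    stop("baseline must contain at least 2 samples", call. = FALSE)
  Q <- .as_quantile(baseline, transformed)
  prep <- if (is.null(sets)) .prep_uni(Q)
          else .prep_multi(Q, .resolve_sets(sets, rownames(Q)))
  .search_gamma(prep, candidates, alpha_threshold, beta)
}

#' Achieved baseline alpha of a fitted model
#'
#' The average proportion of divergent features (or feature sets) per sample
#' when a cohort is coded against the fitted support. With no cohort given the
#' in-sample value stored at fit time is returned; with a cohort it is
#' recomputed by coding that cohort through [predict.divergence_model()],
#' so `baseline_alpha(fit, baseline)` equals the stored value when `baseline`
#' is the fitting cohort.
#'
#' @param model a fitted `divergence_model`.
#' @param cohort optional feature-by-sample matrix to code.
#' @param transformed is `cohort` already on quantile scale?
#' @return a number in \[0, 1\].
#' @export
baseline_alpha <- function(model, cohort = NULL, transformed = FALSE) {
  stopifnot(inherits(model, "divergence_model"))
  if (is.null(cohort)) return(model$achieved_alpha)
  z <- predict(model, cohort, transformed = transformed)
  mean(abs(unclass(z)), na.rm = TRUE)
}

# ---- internals --------------------------------------------------------------

.check_param <- function(x, name, lo, hi, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) stop(sprintf("'%s' must be a single number in %s%g, %g%s", name,
                        if (lo_open) "(" else "[", lo, hi,
                        if (hi_open) ")" else "]"), call. = FALSE)
}

.as_quantile <- function(x, transformed) {
  if (!transformed) return(quantile_transform(x))
  r <- suppressWarnings(range(x, na.rm = TRUE))
  if (!all(is.finite(r)) || r[1] < 0 || r[2] > 1)
    stop("transformed = TRUE but values fall outside [0, 1]", call. = FALSE)
  x
}

# named list of character vectors -> members resolved against feature ids
.resolve_sets <- function(sets, features) {
  if (is.null(sets))
    stop("type = \"multivariate\" requires a 'sets' list", call. = FALSE)
  if (length(sets) == 0L) {    # vacuous collection: 0-row codings downstream
    names(sets) <- character(0)
    return(sets)
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("'sets' must be a list with unique non-empty names", call. = FALSE)
  resolved <- lapply(sets, function(s) unique(as.character(s)))
  n_missing <- vapply(resolved, function(s) sum(!s %in% features), 0L)
  if (any(n_missing > 0L))
    warning(sprintf(
      "dropped %d set member(s) absent from the data across %d set(s)",
      sum(n_missing), sum(n_missing > 0L)), call. = FALSE)
  resolved <- lapply(resolved, function(s) s[s %in% features])
  empty <- lengths(resolved) == 0L
  if (any(empty)) {
    warning(sprintf("skipped %d set(s) with no resolvable members: %s",
                    sum(empty),
                    paste(utils::head(names(resolved)[empty], 5L),
                          collapse = ", ")), call. = FALSE)
    resolved <- resolved[!empty]
  }
  if (length(resolved) == 0L)
    stop("no feature set has resolvable members", call. = FALSE)
  resolved
}

.prep_uni <- function(Q) {
  n <- ncol(Q)
  nd <- vector("list", nrow(Q))
  for (j in seq_len(nrow(Q))) {
    d <- abs(outer(Q[j, ], Q[j, ], "-"))
    diag(d) <- Inf
    nd[[j]] <- t(apply(d, 1L, sort))[, seq_len(n - 1L), drop = FALSE]
  }
  list(type = "univariate", Q = Q, nd = nd, n = n)
}

.prep_multi <- function(Q, sets) {
  n <- ncol(Q)
  entries <- lapply(sets, function(members) {
    pts <- t(Q[members, , drop = FALSE])    # n x |S|
    dfull <- as.matrix(stats::dist(pts))
    ds <- dfull
    diag(ds) <- Inf
    ds <- t(apply(ds, 1L, sort))[, seq_len(n - 1L), drop = FALSE]
    list(members = members, pts = pts, dfull = dfull, dsorted = ds)
  })
  list(type = "multivariate", Q = Q, sets = sets, entries = entries, n = n)
}

.fit_uni <- function(prep, l, beta) {
  Q <- prep$Q
  m <- nrow(Q)
  intervals <- matrix(NA_real_, m, 2L,
                      dimnames = list(rownames(Q), c("lower", "upper")))
  for (j in seq_len(m)) {
    v <- Q[j, ]
    radii <- prep$nd[[j]][, l]
    kept <- .kept_spheres(radii, beta)
    intervals[j, 1L] <- max(0, min(v[kept] - radii[kept]))
    intervals[j, 2L] <- min(1, max(v[kept] + radii[kept]))
  }
  list(features = rownames(Q), intervals = intervals)
}

.fit_multi <- function(prep, l, beta) {
  support <- lapply(prep$entries, function(e) {
    radii <- e$dsorted[, l]
    kept <- .kept_spheres(radii, beta)
    list(members = e$members, centers = e$pts, radii = radii, kept = kept)
  })
  list(set_names = names(prep$sets), sets = prep$sets, support = support)
}

# in-sample alpha at a given (l, beta), reusing precomputed distances
.alpha_at <- function(prep, l, beta) {
  if (prep$type == "univariate") {
    Q <- prep$Q
    div <- 0
    for (j in seq_len(nrow(Q))) {
      v <- Q[j, ]
      radii <- prep$nd[[j]][, l]
      kept <- .kept_spheres(radii, beta)
      lo <- max(0, min(v[kept] - radii[kept]))
      hi <- min(1, max(v[kept] + radii[kept]))
      div <- div + sum(v < lo | v > hi, na.rm = TRUE)
    }
    return(div / (nrow(Q) * ncol(Q)))
  }
  if (length(prep$entries) == 0L) return(0)
  per_set <- vapply(prep$entries, function(e) {
    radii <- e$dsorted[, l]
    kept <- .kept_spheres(radii, beta)
    inside <- e$dfull[, kept, drop = FALSE] <=
      matrix(radii[kept], prep$n, sum(kept), byrow = TRUE)
    sum(rowSums(inside) == 0L)
  }, 0)
  sum(per_set) / (length(prep$entries) * prep$n)
}

.search_gamma <- function(prep, candidates, alpha_threshold, beta) {
  if (length(candidates) == 0L)
    stop("empty gamma candidate list", call. = FALSE)
  if (is.unsorted(candidates, strictly = TRUE))
    stop("gamma candidates must be strictly ascending", call. = FALSE)
  .check_param(alpha_threshold, "alpha_threshold", 0, 1, TRUE, TRUE)
  alphas <- numeric(0)
  selected <- NA_real_
  converged <- FALSE
  for (g in candidates) {
    l <- .knn_l(prep$n, g, warn = FALSE)
    a <- .alpha_at(prep, l, beta)
    alphas[as.character(g)] <- a
    if (a <= alpha_threshold) {
      selected <- g
      converged <- TRUE
      break
    }
  }
  if (!converged) selected <- candidates[length(candidates)]
  structure(list(selected_gamma = selected,
                 candidate_gammas = candidates,
                 alpha_threshold = alpha_threshold,
                 achieved_alpha_per_candidate = alphas,
                 converged = converged),
            class = "gamma_search")
}
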