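#' Code case samples against a fitted baseline model
#'
#' Applies a fitted divergence model to new samples, producing the digitized
#' coding matrix: ternary (-1/0/1) for a univariate model, binary (0/1, one
#' row per feature set) for a multivariate model. Interval boundaries are
#' inclusive, so a value exactly at the baseline interval's edge (or on a
#' sphere's surface) codes 0.
#'
#' Features are matched to the model by id: model features absent from
#' `newdata` are dropped with a warning (for a multivariate model, sets with
#' any missing member are dropped), and an error is raised when nothing
#' overlaps. Row order of the output follows the model, not `newdata`.
#'
#' @param object a fitted `divergence_model` from [divfit()].
#' @param newdata feature-by-sample matrix of case samples (raw by default).
#' @param transformed set `TRUE` when `newdata` is already on quantile scale.
#' @param ... unused.
#' @return an integer matrix of class `divergence_coding` (features or sets in
#'   rows, samples in columns) with attribute `coding_type` `"ternary"` or
#'   `"binary"`.
#' @export
predict.divergence_model <- function(object, newdata, transformed = FALSE,
                                     ...) {
  newdata <- as_omics_matrix(newdata)
  Q <- .as_quantile(newdata, transformed)
  if (inherits(object, "univariate_divergence")) {
    feats <- object$features
    keep <- feats %in% rownames(Q)
    if (!any(keep))
      stop("no overlapping features between model and newdata", call. = FALSE)
    if (!all(keep))
      warning(sprintf("%d model feature(s) absent from newdata were dropped",
                      sum(!keep)), call. = FALSE)
    feats <- feats[keep]
    qs <- Q[feats, , drop = FALSE]
    lo <- object$intervals[feats, "lower"]
    hi <- object$intervals[feats, "upper"]
    z <- (qs > hi) - (qs < lo)
    dimnames(z) <- list(feats, colnames(Q))
    return(new_coding(z, "ternary", object))
  }
  # multivariate: a set is applicable only if every member is present
  support <- object$support
  ok <- vapply(support, function(s) all(s$members %in% rownames(Q)), TRUE)
  if (length(support) > 0L && !any(ok))
    stop("no overlapping features between model and newdata", call. = FALSE)
  if (!all(ok))
    warning(sprintf(
      "%d set(s) with members absent from newdata were dropped", sum(!ok)),
      call. = FALSE)
  support <- support[ok]
  z <- matrix(0L, length(support), ncol(Q),
              dimnames = list(names(support), colnames(Q)))
  for (i in seq_along(support)) {
    s <- support[[i]]
    pts <- Q[s$members, , drop = FALSE]      # |S| x n_samples
    kept <- which(s$kept)
    ck <- t(s$centers[kept, , drop = FALSE]) # |S| x K
    rk <- s$radii[kept]
    for (p in seq_len(ncol(pts))) {
      d <- sqrt(colSums((ck - pts[, p])^2))
      z[i, p] <- as.integer(!any(d <= rk))
    }
  }
  new_coding(z, "binary", object)
}

#' Fit a baseline model and code a case cohort in one call
#'
#' Convenience wrapper around [divfit()] and [predict.divergence_model()]:
#' quantile-transforms both cohorts, calibrates gamma on the baseline under
#' the `alpha` budget (unless `gamma` is fixed), fits the support and codes
#' the case samples.
#'
#' @inheritParams divfit
#' @param cases feature-by-sample matrix of case samples sharing the
#'   baseline's feature space.
#' @return a `divergence_run` list: `model` (the fitted `divergence_model`),
#'   `coding` (the case `divergence_coding`), and `search` (the
#'   `gamma_search`, or `NULL` when `gamma` was fixed).
#' @examples
#' set.seed(7)
#' sim <- simulate_cohorts(n_features = 60, n_baseline = 25, n_cases = 10,
#'                         n_planted = 5, seed = 7)
#' run <- divergence(sim$baseline, sim$cases)
#' run$model$gamma
#' head(divergence_probability(run$coding))
#' @export
divergence <- function(baseline, cases, type = c("univariate", "multivariate"),
                       sets = NULL, alpha = 0.01, beta = 0.95, gamma = NULL,
                       gamma_candidates = default_gamma_candidates(),
                       transformed = FALSE) {
  model <- divfit(baseline, type = type, sets = sets, alpha = alpha,
                  beta = beta, gamma = gamma,
                  gamma_candidates = gamma_candidates,
                  transformed = transformed)
  coding <- predict(model, cases, transformed = transformed)
  structure(list(model = model, coding = coding, search = model$search),
            class = "divergence_run")
}

# ---- divergence_coding ------------------------------------------------------

#' Construct a divergence coding matrix
#'
#' Mostly used internally by [predict.divergence_model()]; exposed so that
#' codings read back from disk or built in scripts carry the same class.
#'
#' @param values integer matrix; entries must lie in \{-1, 0, 1\} for
#'   `type = "ternary"` and \{0, 1\} for `type = "binary"`.
#' @param type `"ternary"` or `"binary"`.
#' @param model optional fitted model; its parameters are stored as provenance.
#' @return `values` with class `divergence_coding`.
#' @export
new_coding <- function(values, type = c("ternary", "binary"), model = NULL) {
  type <- match.arg(type)
  if (!is.matrix(values))
    stop("coding must be a matrix", call. = FALSE)
  allowed <- if (type == "ternary") c(-1L, 0L, 1L) else c(0L, 1L)
  v <- values[!is.na(values)]
  if (!all(v %in% allowed))
    stop(sprintf("%s coding may only contain {%s}", type,
                 paste(allowed, collapse = ", ")), call. = FALSE)
  storage.mode(values) <- "integer"
  prov <- if (!is.null(model))
    list(gamma = model$gamma, beta = model$beta,
         achieved_alpha = model$achieved_alpha,
         n_baseline = model$n_baseline)
  structure(values, coding_type = type, provenance = prov,
            class = c("divergence_coding", "matrix", "array"))
}

#' @export
print.divergence_coding <- function(x, ...) {
  ty <- attr(x, "coding_type")
  cat(sprintf("Divergence coding (%s): %d %s x %d samples\n", ty, nrow(x),
              if (ty == "ternary") "features" else "sets", ncol(x)))
  tab <- table(factor(x, levels = if (ty == "ternary") -1:1 else 0:1))
  cat("  code counts:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n")
  prov <- attr(x, "provenance")
  if (!is.null(prov))
    cat(sprintf("  model: gamma=%g beta=%g baseline alpha=%.4g (n=%d)\n",
                prov$gamma, prov$beta, prov$achieved_alpha, prov$n_baseline))
  invisible(x)
}

# strip class/attrs; validate an arbitrary matrix as a coding
coding_values <- function(x, binary_only = FALSE) {
  ty <- attr(x, "coding_type")
  m <- unclass(x)
  attr(m, "coding_type") <- NULL
  attr(m, "provenance") <- NULL
  if (!is.matrix(m) || !is.numeric(m))
    stop("expected a divergence coding matrix", call. = FALSE)
  v <- m[!is.na(m)]
  if (!all(v %in% c(-1, 0, 1)))
    stop("coding entries must be in {-1, 0, 1}", call. = FALSE)
  if (binary_only) m <- abs(m)
  m
}

# ---- model methods ----------------------------------------------------------

#' @export
print.divergence_model <- function(x, ...) {
  uni <- inherits(x, "univariate_divergence")
  cat(sprintf("%s divergence model\n",
              if (uni) "Univariate" else "Multivariate"))
  cat(sprintf("  %d %s, %d baseline samples\n",
              if (uni) length(x$features) else length(x$support),
              if (uni) "features" else "feature sets", x$n_baseline))
  cat(sprintf("  gamma = %g%s, beta = %g, l = %d\n", x$gamma,
              if (is.null(x$search)) " (fixed)" else " (selected)",
              x$beta, x$l))
  cat(sprintf("  achieved baseline alpha = %.4g\n", x$achieved_alpha))
  if (!is.null(x$search) && !x$search$converged)
    cat("  NOTE: gamma search did not meet the alpha budget\n")
  invisible(x)
}

#' @export
summary.divergence_model <- function(object, ...) {
  out <- list(model = object)
  if (inherits(object, "univariate_divergence")) {
    w <- object$intervals[, "upper"] - object$intervals[, "lower"]
    out$interval_width <- summary(w)
    out$n_full <- sum(object$intervals[, "lower"] == 0 &
                        object$intervals[, "upper"] == 1)
  } else {
    out$set_size <- summary(lengths(object$sets))
    out$kept_fraction <- summary(vapply(object$support,
                                        function(s) mean(s$kept), 0))
  }
  class(out) <- "summary.divergence_model"
  out
}

#' @export
print.summary.divergence_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$interval_width)) {
    cat("  baseline interval widths:\n")
    print(x$interval_width)
    cat(sprintf("  features with full-range [0,1] interval: %d\n", x$n_full))
  } else {
    cat("  set sizes:\n")
    print(x$set_size)
    cat("  fraction of spheres kept per set:\n")
    print(x$kept_fraction)
  }
  invisible(x)
}

#' Extract fitted baseline parameters
#'
#' For a univariate model, the per-feature baseline interval bounds (a
#' two-column matrix `lower`/`upper`); for a multivariate model, a per-set
#' data frame with the number of members, spheres kept after trimming, and
#' the trimming radius threshold actually applied.
#'
#' @param object a fitted `divergence_model`.
#' @param ... unused.
#' @export
coef.divergence_model <- function(object, ...) {
  if (inherits(object, "univariate_divergence"))
    return(object$intervals)
  data.frame(
    set = names(object$support),
    n_members = lengths(object$sets),
    n_kept = vapply(object$support, function(s) sum(s$kept), 0L),
    max_kept_radius = vapply(object$support,
                             function(s) if (any(s$kept))
                               max(s$radii[s$kept]) else NA_real_, 0),
    row.names = NULL)
}

#' Diagnostic plot of a fitted divergence model
#'
#' When the model was fitted with a gamma search, plots the achieved baseline
#' alpha over the evaluated candidates against the alpha budget; otherwise
#' shows the distribution of baseline interval widths (univariate) or kept
#' sphere radii (multivariate).
#'
#' @param x a fitted `divergence_model`.
#' @param ... passed on to the underlying base graphics call.
#' @export
plot.divergence_model <- function(x, ...) {
  s <- x$search
  if (!is.null(s) && length(s$achieved_alpha_per_candidate) > 1L) {
    g <- as.numeric(names(s$achieved_alpha_per_candidate))
    a <- unname(s$achieved_alpha_per_candidate)
    graphics::plot(g, a, type = "b", log = "x", xlab = "gamma",
                   ylab = "achieved baseline alpha",
                   main = "gamma calibration", ...)
    graphics::abline(h = s$alpha_threshold, lty = 2)
    graphics::abline(v = s$selected_gamma, lty = 3)
  } else if (inherits(x, "univariate_divergence")) {
    graphics::hist(x$intervals[, "upper"] - x$intervals[, "lower"],
                   xlab = "baseline interval width",
                   main = "baseline interval widths", ...)
  } else {
    r <- unlist(lapply(x$support, function(s) s$radii[s$kept]))
    graphics::hist(r, xlab = "kept sphere radius",
                   main = "baseline sphere radii", ...)
  }
  invisible(x)
}

#' @export
print.gamma_search <- function(x, ...) {
  cat(sprintf("gamma search over %d candidates (alpha budget %g)\n",
              length(x$candidate_gammas), x$alpha_threshold))
  a <- x$achieved_alpha_per_candidate
  for (nm in names(a))
    cat(sprintf("  gamma = %-5s alpha = %.4g%s\n", nm, a[[nm]],
                if (as.numeric(nm) == x$selected_gamma && x$converged)
                  "  <- selected" else ""))
  if (!x$converged)
    cat(sprintf("  no candidate met the budget; fell back to gamma = %g\n",
                x$selected_gamma))
  invisible(x)
}

#' @export
print.divergence_run <- function(x, ...) {
  print(x$model)
  print(x$coding)
  invisible(x)
}
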