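#' Per-feature divergence probability
#'
#' The fraction of samples in which a feature (or feature set) is divergent,
#' i.e. its coding entry is non-zero. Works for ternary and binary codings.
#'
#' @param coding a `divergence_coding` or plain matrix with entries in
#'   \{-1, 0, 1\}.
#' @param samples optional character or integer vector selecting a subset of
#'   sample columns; must be non-empty and resolvable.
#' @return named numeric vector over features, values in \[0, 1\].
#' @export
divergence_probability <- function(coding, samples = NULL) {
  z <- coding_values(coding)
  if (!is.null(samples)) {
    if (length(samples) == 0L)
      stop("empty sample subset", call. = FALSE)
    if (is.character(samples) && !all(samples %in% colnames(z)))
      stop("unknown sample id(s) in subset", call. = FALSE)
    z <- z[, samples, drop = FALSE]
  }
  if (ncol(z) == 0L) stop("no samples to compute probabilities over",
                          call. = FALSE)
  rowMeans(z != 0, na.rm = TRUE)
}

#' Per-sample divergence counts
#'
#' The size of each sample's divergent feature set under a ternary coding:
#' total number of divergent features plus the split into upper (+1) and
#' lower (-1) divergence. The total is a simple sample-level score of
#' deviation from the baseline.
#'
#' @param coding a ternary `divergence_coding` (features x samples).
#' @return data frame with one row per sample: `sample`, `total`, `upper`,
#'   `lower` (`total = upper + lower`).
#' @export
sample_divergence_counts <- function(coding) {
  z <- coding_values(coding)
  up <- colSums(z == 1L, na.rm = TRUE)
  dn <- colSums(z == -1L, na.rm = TRUE)
  data.frame(sample = colnames(z), total = up + dn, upper = up, lower = dn,
             row.names = NULL)
}

#' Chi-squared screening for differential divergence between two groups
#'
#' For every feature, builds the 2x2 contingency table of divergent vs
#' non-divergent (ternary codes are binarized as non-zero) against the two
#' sample groups and computes the Yates-continuity-corrected chi-squared
#' statistic with 1 degree of freedom. Degenerate tables (a zero row or
#' column marginal, e.g. a feature never divergent in either group) get
#' statistic 0 and p-value 1 and are flagged. P-values are Bonferroni-adjusted
#' over the tested features by default.
#'
#' @param coding a `divergence_coding` (features x samples).
#' @param labels a factor/character vector of group labels named by sample id,
#'   or a two-column data frame (sample id, label). Exactly two distinct
#'   labels must occur among the coding's samples; samples without a label are
#'   ignored.
#' @param adjust multiple-testing correction: `"bonferroni"` (default) or
#'   `"BH"`.
#' @return data frame with one row per feature: divergence probability in
#'   each group, `statistic`, `p_value`, `adjusted_p`, and `degenerate`.
#'   Rows are ordered by ascending p-value, ties broken by descending
#'   statistic.
#' @examples
#' z <- rbind(g1 = c(1, 1, 1, 0, 0, 0), g2 = c(0, 1, 0, 1, 0, 1))
#' colnames(z) <- paste0("s", 1:6)
#' labs <- setNames(rep(c("A", "B"), each = 3), colnames(z))
#' chisq_divergence(z, labs)
#' @export
chisq_divergence <- function(coding, labels, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  z <- coding_values(coding, binary_only = TRUE)
  labels <- .as_labels(labels)
  common <- intersect(colnames(z), names(labels))
  if (length(common) == 0L)
    stop("no coding samples carry a group label", call. = FALSE)
  z <- z[, common, drop = FALSE]
  labels <- factor(as.character(labels[common]))
  if (nlevels(labels) != 2L)
    stop(sprintf("exactly two groups required, got %d", nlevels(labels)),
         call. = FALSE)
  ga <- levels(labels)[1L]
  gb <- levels(labels)[2L]
  na <- sum(labels == ga)
  nb <- sum(labels == gb)
  a <- rowSums(z[, labels == ga, drop = FALSE] != 0, na.rm = TRUE)
  c_ <- rowSums(z[, labels == gb, drop = FALSE] != 0, na.rm = TRUE)
  res <- yates_chisq(a, na - a, c_, nb - c_)
  out <- data.frame(
    feature = rownames(z),
    prob_a = a / na, prob_b = c_ / nb,
    statistic = res$statistic, p_value = res$p_value,
    adjusted_p = stats::p.adjust(res$p_value, method = adjust),
    degenerate = res$degenerate,
    row.names = NULL)
  names(out)[2:3] <- paste0("prob_", c(ga, gb))
  out[order(out$p_value, -out$statistic), , drop = FALSE]
}

#' Yates-corrected chi-squared statistic for 2x2 tables
#'
#' Vectorized over tables given as the four cell counts
#' `rbind(c(a, b), c(d, e))` per table. The continuity correction subtracts
#' `min(0.5, |observed - expected|)` from each cell deviation, so tiny
#' deviations are not over-corrected. Tables with a zero marginal are
#' reported as degenerate with statistic 0 and p-value 1.
#'
#' @param a,b,c,d cell counts: `a`/`b` divergent and non-divergent in group 1,
#'   `c`/`d` the same in group 2 (each may be a vector).
#' @return list with numeric vectors `statistic`, `p_value` and logical
#'   `degenerate`.
#' @export
yates_chisq <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degen <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  e11 <- r1 * c1 / n
  corr <- pmin(0.5, abs(a - e11))     # same |O - E| in every cell of a 2x2
  num <- (abs(a * d - b * c) - corr * n)^2 * n
  den <- r1 * r2 * c1 * c2
  stat <- ifelse(degen, 0, num / den)
  list(statistic = stat,
       p_value = ifelse(degen, 1, stats::pchisq(stat, df = 1,
                                                lower.tail = FALSE)),
       degenerate = degen)
}

#' Co-divergence of feature pairs across two codings
#'
#' For pairs of features from two codings sharing samples (typically a gene's
#' expression coding and a CpG's methylation coding), computes the proportion
#' of samples in which both members of the pair are divergent. When both
#' codings are ternary the proportion is split into concordant (both +1 or
#' both -1) and discordant (both divergent with opposite signs) parts, which
#' always sum to the total.
#'
#' @param coding_a,coding_b divergence codings; samples are matched by id and
#'   their intersection (non-empty) is used.
#' @param pairs two-column data frame or matrix of (feature in `coding_a`,
#'   feature in `coding_b`); pairs with an unresolvable member are skipped
#'   with a warning.
#' @return data frame with one row per resolvable pair: `feature_a`,
#'   `feature_b`, `proportion`, `concordant`, `discordant` (the latter two
#'   `NA` unless both codings are ternary).
#' @export
co_divergence <- function(coding_a, coding_b, pairs) {
  ternary <- identical(attr(coding_a, "coding_type"), "ternary") &&
    identical(attr(coding_b, "coding_type"), "ternary")
  za <- coding_values(coding_a)
  zb <- coding_values(coding_b)
  # without declared types, signs decide: sign information is usable iff
  # both matrices actually carry it
  if (is.null(attr(coding_a, "coding_type")) ||
      is.null(attr(coding_b, "coding_type")))
    ternary <- any(za < 0, na.rm = TRUE) && any(zb < 0, na.rm = TRUE)
  common <- intersect(colnames(za), colnames(zb))
  if (length(common) == 0L)
    stop("codings share no samples", call. = FALSE)
  za <- za[, common, drop = FALSE]
  zb <- zb[, common, drop = FALSE]
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) stop("'pairs' needs two columns", call. = FALSE)
  ok <- pairs[[1L]] %in% rownames(za) & pairs[[2L]] %in% rownames(zb)
  if (!all(ok))
    warning(sprintf("skipped %d unresolvable pair(s)", sum(!ok)),
            call. = FALSE)
  pairs <- pairs[ok, , drop = FALSE]
  n <- length(common)
  prop <- conc <- disc <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- za[pairs[[1L]][i], ]
    y <- zb[pairs[[2L]][i], ]
    both <- x != 0 & y != 0
    prop[i] <- sum(both, na.rm = TRUE) / n
    if (ternary) {
      conc[i] <- sum(both & sign(x) == sign(y), na.rm = TRUE) / n
      disc[i] <- sum(both & sign(x) != sign(y), na.rm = TRUE) / n
    }
  }
  if (!ternary) conc <- disc <- rep(NA_real_, nrow(pairs))
  data.frame(feature_a = pairs[[1L]], feature_b = pairs[[2L]],
             proportion = prop, concordant = conc, discordant = disc,
             row.names = NULL)
}

#' Combine two binary codings by elementwise AND
#'
#' A 1 in the result marks a sample divergent for the feature in both input
#' codings (e.g. divergent in expression and in methylation). Ternary inputs
#' are binarized first. Features and samples are matched by id; the
#' intersection must be non-empty.
#'
#' @param coding_a,coding_b codings sharing feature and sample ids.
#' @return a binary `divergence_coding` over the shared features and samples,
#'   in `coding_a`'s order.
#' @export
combine_codings <- function(coding_a, coding_b) {
  za <- coding_values(coding_a, binary_only = TRUE)
  zb <- coding_values(coding_b, binary_only = TRUE)
  feats <- intersect(rownames(za), rownames(zb))
  smps <- intersect(colnames(za), colnames(zb))
  if (length(feats) == 0L || length(smps) == 0L)
    stop("codings share no features or no samples", call. = FALSE)
  new_coding(za[feats, smps, drop = FALSE] * zb[feats, smps, drop = FALSE],
             "binary")
}

#' Gene-level binary divergence from CpG methylation
#'
#' Rolls CpG-level methylation up to genes: the CpGs mapped to a gene are
#' treated as one multivariate feature when there are at least two of them
#' (binary sphere-support coding), while genes mapped to a single CpG use
#' binarized univariate (interval) coding. Both routes share the same
#' alpha/beta/gamma calibration, run separately for the multivariate and
#' univariate parts. Genes with no CpG present in the matrices are dropped
#' with a warning.
#'
#' @param baseline,cases CpG-by-sample beta-value matrices (values in
#'   \[0, 1\]).
#' @param cpg_to_gene two-column data frame or named character vector mapping
#'   CpG id to gene.
#' @inheritParams divfit
#' @return a binary `divergence_coding`, genes x case samples.
#' @export
gene_methylation_coding <- function(baseline, cases, cpg_to_gene,
                                    alpha = 0.01, beta = 0.95, gamma = NULL,
                                    gamma_candidates =
                                      default_gamma_candidates(),
                                    transformed = FALSE) {
  map <- .as_labels(cpg_to_gene)
  baseline <- as_omics_matrix(baseline)
  cases <- as_omics_matrix(cases)
  present <- names(map) %in% rownames(baseline) &
    names(map) %in% rownames(cases)
  dropped_genes <- setdiff(unique(as.character(map)),
                           unique(as.character(map[present])))
  if (length(dropped_genes) > 0L)
    warning(sprintf("dropped %d gene(s) with no resolvable CpGs",
                    length(dropped_genes)), call. = FALSE)
  map <- map[present]
  if (length(map) == 0L)
    stop("no mapped CpGs found in the matrices", call. = FALSE)
  sets <- split(names(map), as.character(map))
  multi <- sets[lengths(sets) >= 2L]
  single <- sets[lengths(sets) == 1L]

  # transform once on the full matrices: per-sample ranks depend on every
  # CpG in the profile, so rows must not be subset before transforming
  Qb <- .as_quantile(baseline, transformed)
  Qc <- .as_quantile(cases, transformed)

  parts <- list()
  if (length(multi) > 0L) {
    fit <- divfit(Qb, type = "multivariate", sets = multi,
                  alpha = alpha, beta = beta, gamma = gamma,
                  gamma_candidates = gamma_candidates, transformed = TRUE)
    parts$multi <- coding_values(predict(fit, Qc, transformed = TRUE))
  }
  if (length(single) > 0L) {
    cpgs <- unlist(single, use.names = FALSE)
    fit <- divfit(Qb[cpgs, , drop = FALSE], alpha = alpha, beta = beta,
                  gamma = gamma, gamma_candidates = gamma_candidates,
                  transformed = TRUE)
    zt <- abs(coding_values(predict(fit, Qc[cpgs, , drop = FALSE],
                                    transformed = TRUE)))
    rownames(zt) <- names(single)[match(rownames(zt), cpgs)]
    parts$single <- zt
  }
  z <- do.call(rbind, unname(parts))
  new_coding(z[order(rownames(z)), , drop = FALSE], "binary")
}

# labels: named vector, factor, or 2-column data frame -> named character
.as_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2L)
      stop("label data frame needs two columns (sample, label)",
           call. = FALSE)
    out <- as.character(labels[[2L]])
    names(out) <- as.character(labels[[1L]])
    return(out)
  }
  if (is.null(names(labels)))
    stop("labels must be named by sample id", call. = FALSE)
  out <- as.character(labels)
  names(out) <- names(labels)
  out
}
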