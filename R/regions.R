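#' Cluster CpGs by genomic proximity
#'
#' Chains CpGs along each chromosome into clusters in which every pair of
#' adjacent members is at most `max_gap` base pairs apart (single-linkage; a
#' gap of exactly `max_gap` still merges). Positions are 1-based and cluster
#' intervals `[start, end]` are inclusive.
#'
#' @param annotation data frame with columns `cpg_id`, `chromosome`,
#'   `position` (1-based bp); extra columns (e.g. `gene`) are ignored here.
#'   Duplicate (chromosome, position, cpg_id) rows are collapsed with a
#'   warning.
#' @param max_gap maximum allowed gap between adjacent cluster members in bp
#'   (default 300).
#' @return list with `clusters` (data frame: `cluster_id`, `chromosome`,
#'   `start`, `end`, `n_cpgs`) and `members` (data frame: `cluster_id`,
#'   `cpg_id`, `position`, ordered by position within cluster).
#' @examples
#' ann <- data.frame(cpg_id = paste0("cg", 1:4), chromosome = "chr1",
#'                   position = c(100, 350, 700, 1100))
#' cluster_cpgs(ann)$clusters  # {100,350}, {700}, {1100}
#' @export
cluster_cpgs <- function(annotation, max_gap = 300L) {
  annotation <- .check_annotation(annotation)
  if (max_gap < 0) stop("'max_gap' must be non-negative", call. = FALSE)
  dup <- duplicated(annotation[c("chromosome", "position", "cpg_id")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicated annotation row(s)", sum(dup)),
            call. = FALSE)
    annotation <- annotation[!dup, , drop = FALSE]
  }
  ord <- order(annotation$chromosome, annotation$position)
  annotation <- annotation[ord, , drop = FALSE]
  new_chrom <- c(TRUE, annotation$chromosome[-1L] !=
                   annotation$chromosome[-nrow(annotation)])
  gap <- c(0L, diff(annotation$position))
  cl <- cumsum(new_chrom | gap > max_gap)
  members <- data.frame(cluster_id = sprintf("cluster_%d", cl),
                        cpg_id = annotation$cpg_id,
                        position = annotation$position,
                        row.names = NULL)
  clusters <- data.frame(
    cluster_id = sprintf("cluster_%d", unique(cl)),
    chromosome = tapply(annotation$chromosome, cl, `[`, 1L),
    start = as.integer(tapply(annotation$position, cl, min)),
    end = as.integer(tapply(annotation$position, cl, max)),
    n_cpgs = as.integer(tapply(annotation$position, cl, length)),
    row.names = NULL)
  list(clusters = clusters, members = members)
}

#' Average divergence score of CpG clusters
#'
#' Scores each cluster by the average divergence of its member CpGs over all
#' samples: the sum of binarized coding entries across member CpGs and
#' samples, divided by (number of samples x number of members). Cluster
#' members missing from the coding are dropped (with a warning) and the
#' member count adjusted; clusters left without members are skipped.
#'
#' @param coding CpG-by-sample coding (ternary entries are binarized).
#' @param clusters result of [cluster_cpgs()], or any list with a `members`
#'   data frame holding `cluster_id` and `cpg_id`.
#' @return data frame: `cluster_id`, `n_members` (resolvable members),
#'   `score` in \[0, 1\].
#' @export
cluster_divergence_score <- function(coding, clusters) {
  z <- coding_values(coding, binary_only = TRUE)
  members <- .cluster_members(clusters)
  ok <- members$cpg_id %in% rownames(z)
  if (!all(ok))
    warning(sprintf("%d cluster member(s) missing from the coding",
                    sum(!ok)), call. = FALSE)
  members <- members[ok, , drop = FALSE]
  lost <- setdiff(unique(.cluster_members(clusters)$cluster_id),
                  unique(members$cluster_id))
  if (length(lost) > 0L)
    warning(sprintf("skipped %d cluster(s) with no resolvable members",
                    length(lost)), call. = FALSE)
  if (nrow(members) == 0L)
    stop("no cluster member resolves in the coding", call. = FALSE)
  row_total <- rowSums(z, na.rm = TRUE)[members$cpg_id]
  n <- ncol(z)
  sums <- tapply(row_total, members$cluster_id, sum)
  sizes <- tapply(row_total, members$cluster_id, length)
  ids <- unique(members$cluster_id)   # keep genomic order
  data.frame(cluster_id = ids,
             n_members = as.integer(sizes[ids]),
             score = as.numeric(sums[ids]) / (n * as.numeric(sizes[ids])),
             row.names = NULL)
}

#' Permutation p-values for cluster divergence scores
#'
#' Builds a null distribution for the cluster scores by permuting the
#' CpG-to-row assignment of the coding matrix (the cluster structure along
#' the genome stays fixed, the divergence profiles are shuffled across CpGs)
#' and recomputing every cluster score. Because the score of a cluster with
#' many members has smaller variance than a singleton's, null scores are
#' pooled only across clusters of equal member count (size-stratified null).
#' P-values use the add-one rule `p = (1 + b) / (1 + B)` where `b` counts
#' null scores at or above the observed score among the `B` null scores of
#' that stratum, so p is never zero.
#'
#' @inheritParams cluster_divergence_score
#' @param n_permutations number of label permutations (default 200).
#' @param seed integer seed driving the permutation sequence; recorded in the
#'   output attributes.
#' @return the [cluster_divergence_score()] data frame with an extra
#'   `p_value` column; attributes `n_permutations` and `seed`.
#' @export
cluster_permutation_pvalues <- function(coding, clusters,
                                        n_permutations = 200L, seed = 1L) {
  if (n_permutations < 1L)
    stop("'n_permutations' must be at least 1", call. = FALSE)
  obs <- cluster_divergence_score(coding, clusters)
  z <- coding_values(coding, binary_only = TRUE)
  members <- .cluster_members(clusters)
  members <- members[members$cpg_id %in% rownames(z), , drop = FALSE]
  n <- ncol(z)
  row_total <- rowSums(z, na.rm = TRUE)       # permuting labels permutes this
  idx <- match(members$cpg_id, rownames(z))
  cl_f <- factor(members$cluster_id, levels = obs$cluster_id)
  sizes <- obs$n_members

  null_scores <- matrix(NA_real_, nrow(obs), n_permutations)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(length(row_total))
    tot <- row_total[perm][idx]
    null_scores[, b] <- as.numeric(
      tapply(tot, cl_f, sum)) / (n * sizes)
  }
  p <- numeric(nrow(obs))
  for (s in unique(sizes)) {
    rows <- which(sizes == s)
    pool <- null_scores[rows, , drop = FALSE]
    B <- length(pool)
    for (r in rows)
      p[r] <- (1 + sum(pool >= obs$score[r])) / (1 + B)
  }
  obs$p_value <- p
  attr(obs, "n_permutations") <- as.integer(n_permutations)
  attr(obs, "seed") <- as.integer(seed)
  obs
}

.cluster_members <- function(clusters) {
  m <- if (is.data.frame(clusters)) clusters else clusters$members
  if (is.null(m) || !all(c("cluster_id", "cpg_id") %in% names(m)))
    stop("'clusters' must provide a members table with cluster_id and cpg_id",
         call. = FALSE)
  m
}

.check_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  need <- c("cpg_id", "chromosome", "position")
  if (!all(need %in% names(annotation)))
    stop(sprintf("annotation needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (nrow(annotation) == 0L)
    stop("empty CpG annotation", call. = FALSE)
  if (any(annotation$position < 0) || anyNA(annotation$position))
    stop("CpG positions must be non-negative and non-missing", call. = FALSE)
  annotation$position <- as.integer(annotation$position)
  annotation$chromosome <- as.character(annotation$chromosome)
  annotation$cpg_id <- as.character(annotation$cpg_id)
  annotation
}
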