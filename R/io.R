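# Plain-text I/O for all artifact types: feature-by-sample matrices and
# codings as TSV (first column = feature id, header = sample ids), gene sets
# as GMT or two-column TSV, group labels and CpG annotations as TSV, fitted
# models as JSON, clusters as BED-like TSV.

#' Read a feature-by-sample matrix from TSV/CSV
#'
#' @param path file path; first column holds feature ids, the header row
#'   sample ids.
#' @param sep field separator (`"\t"` default; use `","` for CSV).
#' @return numeric matrix with feature/sample dimnames.
#' @export
read_omics_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L)
    stop(sprintf("malformed matrix file '%s': need id column plus samples",
                 path), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("non-numeric entries in matrix file '%s'", path),
         call. = FALSE)
  rownames(m) <- as.character(df[[1L]])
  as_omics_matrix(m)
}

#' Write a feature-by-sample matrix (or coding) to TSV/CSV
#'
#' @param x numeric matrix or `divergence_coding`.
#' @param path output file path.
#' @param sep field separator.
#' @param id_col name for the feature-id column (default `"feature"`).
#' @export
write_omics_matrix <- function(x, path, sep = "\t", id_col = "feature") {
  m <- if (inherits(x, "divergence_coding")) coding_values(x) else x
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a divergence coding written by [write_omics_matrix()]
#'
#' @inheritParams read_omics_matrix
#' @param type `"ternary"` or `"binary"`; inferred from the values when
#'   `NULL` (any negative entry implies ternary).
#' @return a `divergence_coding`.
#' @export
read_coding <- function(path, sep = "\t", type = NULL) {
  m <- read_omics_matrix(path, sep = sep)
  if (is.null(type))
    type <- if (any(m < 0, na.rm = TRUE)) "ternary" else "binary"
  new_coding(m, type)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member ids. Descriptions
#' are discarded.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("empty GMT file '%s'", path),
                                call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop(sprintf("malformed GMT line(s) %s in '%s' (need name, description, members)",
                 paste(utils::head(which(bad), 3L), collapse = ", "), path),
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop(sprintf("duplicated set names in '%s'", path), call. = FALSE)
  sets
}

#' Read feature sets from a two-column TSV (set, member)
#'
#' @param path TSV path with a header row.
#' @return named list of character vectors.
#' @export
read_feature_sets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop(sprintf("'%s' needs two columns (set, member)", path), call. = FALSE)
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read sample group labels from a two-column TSV (sample_id, label)
#'
#' @param path TSV path with a header row.
#' @return character vector of labels named by sample id.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  .as_labels(df)
}

#' Read a CpG annotation table
#'
#' Expects a TSV with a header and at least `cpg_id`, `chromosome`,
#' `position` columns; optional `gene` and `distance` columns are carried
#' through.
#'
#' @param path TSV path.
#' @return data frame suitable for [cluster_cpgs()].
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  .check_annotation(df)
}

#' Serialize a fitted divergence model to JSON
#'
#' The document carries the parameters (gamma, beta, l, achieved alpha),
#' per-feature intervals (univariate) or per-set centers/radii/kept flags
#' (multivariate), identifiers, and fit provenance (baseline sample count,
#' timestamp). [read_divergence_model()] restores a model that predicts
#' identically.
#'
#' @param model a fitted `divergence_model`.
#' @param path output JSON path.
#' @export
write_divergence_model <- function(model, path) {
  stopifnot(inherits(model, "divergence_model"))
  uni <- inherits(model, "univariate_divergence")
  doc <- list(
    type = if (uni) "univariate" else "multivariate",
    gamma = model$gamma, beta = model$beta, l = model$l,
    achieved_alpha = model$achieved_alpha,
    n_baseline = model$n_baseline,
    fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(model$search))
    doc$search <- unclass(model$search)
  if (uni) {
    doc$features <- model$features
    doc$lower <- unname(model$intervals[, "lower"])
    doc$upper <- unname(model$intervals[, "upper"])
  } else {
    doc$sets <- lapply(model$support, function(s)
      list(members = s$members, centers = unname(s$centers),
           radii = unname(s$radii), kept = unname(s$kept)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Restore a divergence model from JSON
#'
#' @param path JSON path written by [write_divergence_model()].
#' @return a `divergence_model`.
#' @export
read_divergence_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  uni <- identical(doc$type, "univariate")
  fit <- list(gamma = doc$gamma, beta = doc$beta, l = as.integer(doc$l),
              achieved_alpha = doc$achieved_alpha,
              n_baseline = as.integer(doc$n_baseline),
              search = NULL, call = NULL)
  if (!is.null(doc$search)) {
    s <- doc$search
    s$achieved_alpha_per_candidate <-
      unlist(s$achieved_alpha_per_candidate)
    fit$search <- structure(s, class = "gamma_search")
  }
  if (uni) {
    fit$features <- doc$features
    fit$intervals <- cbind(lower = doc$lower, upper = doc$upper)
    rownames(fit$intervals) <- doc$features
    class(fit) <- c("univariate_divergence", "divergence_model")
  } else {
    fit$support <- lapply(doc$sets, function(s) {
      centers <- as.matrix(s$centers)
      colnames(centers) <- NULL
      list(members = s$members, centers = centers,
           radii = as.numeric(s$radii), kept = as.logical(s$kept))
    })
    fit$sets <- lapply(fit$support, function(s) s$members)
    fit$set_names <- names(doc$sets)
    class(fit) <- c("multivariate_divergence", "divergence_model")
  }
  fit
}

#' Write clusters with scores to a BED-like TSV
#'
#' Columns: chromosome, start, end, cluster_id, n_cpgs, and any score /
#' p-value columns present in `scores`. Positions stay 1-based inclusive, as
#' in the annotation.
#'
#' @param clusters result of [cluster_cpgs()].
#' @param path output TSV path.
#' @param scores optional data frame from [cluster_divergence_score()] or
#'   [cluster_permutation_pvalues()], joined on `cluster_id`.
#' @export
write_clusters <- function(clusters, path, scores = NULL) {
  out <- clusters$clusters
  if (!is.null(scores))
    out <- merge(out, scores[setdiff(names(scores), "n_members")],
                 by = "cluster_id", sort = FALSE)
  out <- out[c("chromosome", "start", "end", "cluster_id",
               setdiff(names(out), c("chromosome", "start", "end",
                                     "cluster_id")))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
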