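#' Scaled rank (quantile) transformation with zero preservation
#'
#' Converts each sample (column) of a feature-by-sample matrix to normalized
#' ranks on \[0, 1\]. For a value `x[j]` in a column `x`, the transformed value
#' is the number of positive entries less than or equal to `x[j]`, divided by
#' the total number of positive entries in that column. Zeros map exactly to
#' zero, so the zero-valued mass typical of RNA-seq counts/TPM is preserved;
#' the largest positive entry of a column maps exactly to 1. No pooling across
#' samples takes place: each column is transformed independently.
#'
#' Missing values are propagated (a missing raw value yields a missing
#' quantile) and are excluded from both the numerator and denominator counts.
#' A column with no positive entries maps to all zeros.
#'
#' @param x numeric matrix, features in rows, samples in columns. All entries
#'   must be non-negative and finite (or `NA`). Dimnames are carried over.
#' @return numeric matrix of the same dimensions with entries in \[0, 1\].
#' @examples
#' m <- cbind(s1 = c(a = 0, b = 5, c = 10, d = 20))
#' quantile_transform(m)  # 0, 1/3, 2/3, 1
#' @export
quantile_transform <- function(x) {
  x <- as_omics_matrix(x)
  if (ncol(x) == 0L || nrow(x) == 0L)
    stop("empty matrix: nothing to transform", call. = FALSE)
  bad <- which(!is.na(x) & (x < 0 | !is.finite(x)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "negative or non-finite value at feature '%s', sample '%s'",
      rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]), call. = FALSE)
  }
  q <- apply(x, 2L, .quantile_col)
  dim(q) <- dim(x)
  dimnames(q) <- dimnames(x)
  q
}

# one column: rank among positive entries with ties sharing the max count
.quantile_col <- function(v) {
  out <- numeric(length(v))
  out[is.na(v)] <- NA_real_
  pos <- which(!is.na(v) & v > 0)
  if (length(pos) == 0L) return(out)   # all-zero (or all-NA) column guard
  out[pos] <- rank(v[pos], ties.method = "max") / length(pos)
  out
}

# Coerce input to a clean numeric matrix with unique dimnames; shared by all
# entry points so validation lives in one place.
as_omics_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric feature-by-sample matrix", call. = FALSE)
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty matrix: no features or no samples", call. = FALSE)
  if (is.null(rownames(x)))
    rownames(x) <- paste0("f", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicated feature ids in matrix", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids in matrix", call. = FALSE)
  x
}

# TRUE when a matrix already looks quantile-transformed
.is_quantile_scale <- function(x) {
  r <- range(x, na.rm = TRUE)
  r[1] >= 0 && r[2] <= 1
}
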