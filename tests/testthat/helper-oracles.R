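# Independent brute-force oracles. Deliberately naive (double/triple loops,
# direct set-cardinality evaluation) and kept free of any package internals
# so they can disagree with the implementation.

oracle_quantile <- function(x) {
  q <- x * 0
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    den <- sum(!is.na(v) & v > 0)
    for (i in seq_len(nrow(x))) {
      if (is.na(v[i])) { q[i, j] <- NA_real_; next }
      q[i, j] <- if (den == 0L || v[i] == 0) 0 else
        sum(!is.na(v) & v > 0 & v <= v[i]) / den
    }
  }
  q
}

# distance from each point (rows of pts) to its l-th nearest other point
oracle_knn_radii <- function(pts, l) {
  n <- nrow(pts)
  vapply(seq_len(n), function(k) {
    d <- vapply(seq_len(n), function(i)
      sqrt(sum((pts[k, ] - pts[i, ])^2)), 0)
    sort(d[-k])[l]
  }, 0)
}

oracle_trim <- function(radii, beta) {
  radii <= stats::quantile(radii, beta, names = FALSE)
}

# is `point` inside the union of kept spheres?
oracle_inside <- function(point, centers, radii, kept) {
  for (k in which(kept)) {
    if (sqrt(sum((point - centers[k, ])^2)) <= radii[k]) return(TRUE)
  }
  FALSE
}

# univariate interval from 1-D baseline values
oracle_interval <- function(v, l, beta) {
  r <- oracle_knn_radii(matrix(v, ncol = 1), l)
  kept <- oracle_trim(r, beta)
  c(lower = max(0, min(v[kept] - r[kept])),
    upper = min(1, max(v[kept] + r[kept])))
}

# textbook Yates-corrected chi-square for one 2x2 table, via per-cell formula
oracle_yates <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(statistic = 0, p_value = 1))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  corr <- min(0.5, abs(tab[1, 1] - E[1, 1]))
  stat <- sum((abs(tab - E) - corr)^2 / E)
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# single-linkage clustering as transitive closure of the <= max_gap relation
oracle_clusters <- function(chrom, pos, max_gap) {
  n <- length(pos)
  adj <- outer(chrom, chrom, "==") & abs(outer(pos, pos, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  match(comp, unique(comp[order(chrom, pos)]))
}

oracle_codiv <- function(x, y) {
  n <- length(x)
  prop <- conc <- disc <- 0
  for (i in seq_len(n)) {
    if (x[i] != 0 && y[i] != 0) {
      prop <- prop + 1
      if (sign(x[i]) == sign(y[i])) conc <- conc + 1 else disc <- disc + 1
    }
  }
  c(proportion = prop / n, concordant = conc / n, discordant = disc / n)
}

oracle_cluster_score <- function(z, member_rows) {
  s <- 0
  for (j in member_rows) for (i in seq_len(ncol(z)))
    s <- s + abs(z[j, i])
  s / (ncol(z) * length(member_rows))
}

# small random non-negative matrix with ties and zeros
rand_omics <- function(m, n, zero_frac = 0.2, max_val = 20L) {
  x <- matrix(sample.int(max_val, m * n, replace = TRUE), m, n)
  x[matrix(stats::runif(m * n) < zero_frac, m, n)] <- 0
  dimnames(x) <- list(sprintf("f%03d", seq_len(m)),
                      sprintf("s%03d", seq_len(n)))
  storage.mode(x) <- "double"
  x
}

rand_quantile_matrix <- function(m, n) {
  x <- matrix(stats::runif(m * n), m, n,
              dimnames = list(sprintf("f%03d", seq_len(m)),
                              sprintf("s%03d", seq_len(n))))
  x
}

rand_ternary <- function(m, n, p = c(0.2, 0.6, 0.2)) {
  z <- matrix(sample(c(-1L, 0L, 1L), m * n, replace = TRUE, prob = p), m, n,
              dimnames = list(sprintf("f%03d", seq_len(m)),
                              sprintf("s%03d", seq_len(n))))
  z
}
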