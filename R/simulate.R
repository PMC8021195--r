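#' Simulate baseline and case cohorts with planted divergent features
#'
#' Generates feature-by-sample matrices emulating the two omics modalities the
#' divergence workflow targets, with a known subset of features made truly
#' divergent in the case cohort so that recovery can be scored against ground
#' truth.
#'
#' Expression-like data are zero-inflated log-normal: each feature has its own
#' log-mean (drawn once from N(`mu`, `tau`)) and log-SD `sigma`. Dropout is
#' tied to expression level, as in real RNA-seq: feature `j` is zeroed with
#' probability `2 * zero_inflation * (1 - pnorm(meanlog_j, mu, tau))` (capped at
#' 1), so lowly expressed features carry most of the zero mass while the
#' cohort-wide zero fraction averages `zero_inflation`.
#'
#' The planted effect is a displacement on the quantile scale, the scale the
#' divergence coding operates on. For expression, a planted feature sitting at
#' percentile `q0 = pnorm(meanlog_j, mu, tau)` of the expression distribution
#' has its case log-mean moved to the `q0 + direction * effect_size`
#' percentile (so `effect_size = 0.5` moves a median-expressed feature into
#' the top of the within-sample ranking); dropout follows the shifted level.
#' Planted features are sampled only from features with enough rank headroom
#' to express the full shift -- a feature already at the top of the ranking
#' cannot move further up, and with zero inflation the baseline interval's
#' lower end is typically 0, masking downward shifts of lowly expressed
#' features (hence the `"up"` default for expression). For methylation the
#' beta-value scale is already \[0, 1\]: planted case features are shifted by
#' `effect_size` directly, clipped to \[0, 1\] with a warning when clipping
#' occurs.
#'
#' `epimutation_rate` adds genome-wide stochastic drift to the methylation
#' case cohort: each case entry is, with that probability, redrawn uniformly
#' on \[0, 1\], independently across CpGs and samples. This emulates the
#' diffuse methylation instability of tumours, affects every CpG
#' exchangeably (so it carries no regional signal), and gives cluster-level
#' scores enough resolution to study the permutation null; without it a
#' calibrated coding diverges almost nowhere and region scores are nearly
#' all zero.
#'
#' @param n_features,n_baseline,n_cases dimensions of the generated matrices.
#' @param n_planted number of truly divergent case features.
#' @param effect_size planted displacement in quantile-scale units (see
#'   Details); default 0.5, a large effect.
#' @param zero_inflation probability that an expression entry is 0 (ignored
#'   for methylation).
#' @param modality `"expression"` or `"methylation"`.
#' @param direction planted shift direction: `"up"`, `"down"` or `"both"`
#'   (random per feature). Defaults to `"up"` for expression, `"both"` for
#'   methylation.
#' @param mu,tau,sigma expression hyper-parameters: feature log-means are
#'   drawn from `N(mu, tau)` (between-feature spread) and entries from
#'   `Lognormal(meanlog_j, sigma)` (within-feature, between-sample
#'   variability). The defaults `tau = 2`, `sigma = 0.4` reflect that in real
#'   RNA-seq the dynamic range across genes is far wider than a gene's
#'   between-sample variability, which keeps within-sample ranks stable.
#' @param epimutation_rate probability that a methylation case entry is
#'   redrawn uniformly on \[0, 1\] (genome-wide drift; 0 disables; ignored
#'   for expression).
#' @param seed integer seed; identical seeds reproduce identical cohorts.
#' @return list with `baseline`, `cases` (numeric matrices with feature and
#'   sample ids), `planted` (character vector of planted feature ids) and
#'   `directions` (+1/-1 per planted feature).
#' @examples
#' sim <- simulate_cohorts(n_features = 50, n_baseline = 20, n_cases = 10,
#'                         n_planted = 5, seed = 1)
#' dim(sim$baseline); sim$planted
#' @export
simulate_cohorts <- function(n_features = 200L, n_baseline = 50L,
                             n_cases = 50L, n_planted = 20L,
                             effect_size = 0.5, zero_inflation = 0.25,
                             modality = c("expression", "methylation"),
                             direction = NULL, mu = 3, tau = 2, sigma = 0.4,
                             epimutation_rate = 0, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(direction))
    direction <- if (modality == "expression") "up" else "both"
  direction <- match.arg(direction, c("up", "down", "both"))
  if (n_planted > n_features)
    stop("more planted features than features", call. = FALSE)
  .check_param(zero_inflation, "zero_inflation", 0, 1)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)

  features <- sprintf("f%04d", seq_len(n_features))
  clipped <- FALSE
  if (modality == "expression") {
    .check_param(effect_size, "effect_size", 0, 0.99)
    meanlog <- stats::rnorm(n_features, mu, tau)
    q0 <- stats::pnorm(meanlog, mu, tau)
    up_ok <- q0 <= 0.995 - effect_size
    down_ok <- q0 >= 0.005 + effect_size
    feasible <- switch(direction, up = up_ok, down = down_ok,
                       both = up_ok | down_ok)
    if (n_planted > sum(feasible))
      stop("not enough features with rank headroom for the planted shift",
           call. = FALSE)
    planted <- sort(sample(features[feasible], n_planted))
    pi <- match(planted, features)
    dirs <- vapply(pi, function(i) switch(direction, up = 1, down = -1,
      both = if (up_ok[i] && down_ok[i]) sample(c(-1, 1), 1L)
             else if (up_ok[i]) 1 else -1), 0)
  } else {
    planted <- sort(sample(features, n_planted))
    dirs <- switch(direction,
                   up = rep(1, n_planted),
                   down = rep(-1, n_planted),
                   both = sample(c(-1, 1), n_planted, replace = TRUE))
  }
  names(dirs) <- planted

  if (modality == "expression") {
    # quantile-scale shift realised as a move along the feature log-mean
    # distribution: percentile q0 -> q0 + dir * effect_size
    ml_shifted <- meanlog
    i <- match(planted, features)
    q1 <- pmin(0.995, pmax(0.005, q0[i] + dirs * effect_size))
    ml_shifted[i] <- mu + tau * stats::qnorm(q1)
    gen <- function(n_samples, shifted) {
      ml <- if (shifted) ml_shifted else meanlog
      vals <- matrix(stats::rlnorm(n_features * n_samples,
                                   meanlog = rep(ml, n_samples),
                                   sdlog = sigma),
                     n_features, n_samples)
      p_zero <- pmin(1, 2 * zero_inflation * stats::pnorm(ml, mu, tau,
                                                          lower.tail = FALSE))
      zero <- matrix(stats::runif(n_features * n_samples) <
                       rep(p_zero, n_samples),
                     n_features, n_samples)
      vals[zero] <- 0
      vals
    }
  } else {
    hyper <- stats::runif(n_features) < 0.5
    shp1 <- ifelse(hyper, 18, 2)
    shp2 <- ifelse(hyper, 2, 18)
    .check_param(epimutation_rate, "epimutation_rate", 0, 1)
    gen <- function(n_samples, shifted) {
      vals <- matrix(stats::rbeta(n_features * n_samples,
                                  rep(shp1, n_samples), rep(shp2, n_samples)),
                     n_features, n_samples)
      if (shifted) {
        if (epimutation_rate > 0) {
          hit <- matrix(stats::runif(n_features * n_samples) <
                          epimutation_rate, n_features, n_samples)
          vals[hit] <- stats::runif(sum(hit))
        }
        if (length(planted) > 0L) {
          i <- match(planted, features)
          vals[i, ] <- vals[i, ] + dirs * effect_size
          if (any(vals < 0 | vals > 1)) {
            clipped <<- TRUE
            vals <- pmax(pmin(vals, 1), 0)
          }
        }
      }
      vals
    }
  }

  baseline <- gen(n_baseline, shifted = FALSE)
  cases <- gen(n_cases, shifted = TRUE)
  if (clipped)
    warning("planted methylation shifts were clipped to [0, 1]",
            call. = FALSE)
  dimnames(baseline) <- list(features,
                             sprintf("base%03d", seq_len(n_baseline)))
  dimnames(cases) <- list(features, sprintf("case%03d", seq_len(n_cases)))
  list(baseline = baseline, cases = cases, planted = planted,
       directions = dirs)
}

#' Simulate a CpG annotation with known cluster structure
#'
#' Places CpGs along chromosomes so that the true clustering at gap threshold
#' `max_gap` is known by construction: within a planned cluster adjacent CpGs
#' are 20..`max_gap` bp apart, between clusters the gap is strictly larger
#' than `max_gap`.
#'
#' @param n_cpgs total number of CpGs.
#' @param n_chromosomes number of chromosomes to spread clusters over.
#' @param max_cluster_size planned cluster sizes are drawn uniformly from
#'   1..`max_cluster_size`.
#' @param max_gap the gap threshold the geometry is built around (default 300).
#' @param seed integer seed.
#' @return list with `annotation` (data frame: `cpg_id`, `chromosome`,
#'   `position`, `gene`) and `truth` (character vector: true cluster id per
#'   CpG, named by `cpg_id`).
#' @export
simulate_cpg_annotation <- function(n_cpgs = 500L, n_chromosomes = 3L,
                                    max_cluster_size = 5L, max_gap = 300L,
                                    seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  sizes <- integer(0)
  while (sum(sizes) < n_cpgs)
    sizes <- c(sizes, sample.int(max_cluster_size, 1L))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_cpgs)
  sizes <- sizes[sizes > 0L]
  chrom <- sort(rep_len(sprintf("chr%d", seq_len(n_chromosomes)),
                        length(sizes)))
  pos <- integer(0); cl <- character(0); chr_out <- character(0)
  for (ch in unique(chrom)) {
    at <- 1000L
    for (k in which(chrom == ch)) {
      gaps <- if (sizes[k] > 1L)
        sample(20:max_gap, sizes[k] - 1L, replace = TRUE) else integer(0)
      p <- at + c(0L, cumsum(gaps))
      pos <- c(pos, p)
      cl <- c(cl, rep(sprintf("true_%d", k), sizes[k]))
      chr_out <- c(chr_out, rep(ch, sizes[k]))
      at <- p[length(p)] + max_gap + sample(50:5000, 1L)
    }
  }
  ids <- sprintf("cg%05d", seq_along(pos))
  annotation <- data.frame(cpg_id = ids, chromosome = chr_out,
                           position = pos,
                           gene = sprintf("gene%03d",
                                          as.integer(factor(cl))),
                           row.names = NULL)
  truth <- stats::setNames(cl, ids)
  list(annotation = annotation, truth = truth)
}
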