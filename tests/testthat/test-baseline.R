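# helpers to build 1-row (1-D) baselines in quantile space
qmat1 <- function(v) matrix(v, 1, length(v),
                            dimnames = list("g1", paste0("n", seq_along(v))))

test_that("1-D sphere radii equal brute-force kNN distances", {
  base <- qmat1(seq(0.1, 1, by = 0.1))
  s <- fit_support_for_set(base, "g1", gamma = 0.2, beta = 1,
                           transformed = TRUE)
  expect_equal(s$l, 2L)
  # interior points have both immediate neighbours at 0.1; endpoints reach
  # their 2nd neighbour at 0.2
  expect_equal(unname(s$radii), c(0.2, rep(0.1, 8), 0.2))
  expect_equal(unname(s$radii),
               unname(oracle_knn_radii(t(base), 2L)))
  expect_true(all(s$kept))
})

test_that("identical baseline points give zero radii and a point support", {
  base <- qmat1(rep(0.4, 5))
  s <- suppressWarnings(fit_support_for_set(base, "g1", gamma = 0.3,
                                            beta = 1, transformed = TRUE))
  expect_equal(unname(s$radii), rep(0, 5))
  expect_true(all(s$kept))
  expect_equal(code_point(s, 0.4), 0L)   # only the point itself is inside
  expect_equal(code_point(s, 0.41), 1L)

  fit <- suppressWarnings(divfit(base, gamma = 0.3, beta = 1,
                                 transformed = TRUE))
  expect_equal(unname(fit$intervals["g1", ]), c(0.4, 0.4))
})

test_that("2-D support radii and membership match the brute-force oracle", {
  pts <- rbind(c(0.4, 0.4), c(0.5, 0.5), c(0.6, 0.6), c(0.5, 0.4))
  base <- matrix(t(pts), 2, 4,
                 dimnames = list(c("g1", "g2"), paste0("n", 1:4)))
  s <- suppressWarnings(fit_support_for_set(base, c("g1", "g2"),
                                            gamma = 0.25, beta = 1,
                                            transformed = TRUE))
  expect_equal(s$l, 1L)
  expect_equal(unname(s$radii), unname(oracle_knn_radii(pts, 1L)),
               tolerance = 1e-12)
  expect_equal(unname(s$radii[2]), 0.1)  # (0.5,0.5) -> (0.5,0.4)
  expect_equal(unname(s$radii[1]), sqrt(0.01 + 0))  # (0.4,0.4) -> (0.5,0.4)
  # membership of arbitrary query points equals the sphere-union oracle
  set.seed(411)
  for (rep in 1:50) {
    p <- stats::runif(2)
    expect_equal(code_point(s, p),
                 as.integer(!oracle_inside(p, pts, s$radii, s$kept)))
  }
})

test_that("support membership matches the oracle on random instances", {
  set.seed(412)
  for (rep in 1:40) {
    n <- sample(5:30, 1)
    d <- sample(1:5, 1)
    Q <- rand_quantile_matrix(d, n)
    gamma <- stats::runif(1, 0.05, 0.6)
    beta <- sample(c(1, stats::runif(1, 0.7, 1)), 1)
    s <- suppressWarnings(fit_support_for_set(Q, rownames(Q), gamma, beta,
                                              transformed = TRUE))
    l <- max(1, floor(n * gamma))
    r <- oracle_knn_radii(t(Q), l)
    expect_equal(unname(s$radii), unname(r), tolerance = 1e-12)
    expect_equal(unname(s$kept), unname(oracle_trim(r, beta)))
    for (k in 1:5) {
      p <- stats::runif(d)
      expect_equal(code_point(s, p),
                   as.integer(!oracle_inside(p, t(Q), s$radii, s$kept)))
    }
  }
})

test_that("univariate intervals match the brute-force interval oracle", {
  # spec-style mixed baseline with a zero cluster
  base <- qmat1(c(0, 0, 0, 0.9, 1.0))
  fit <- suppressWarnings(divfit(base, gamma = 0.4, beta = 1,
                                 transformed = TRUE))
  expect_equal(unname(fit$intervals["g1", ]),
               unname(oracle_interval(c(0, 0, 0, 0.9, 1.0), 2L, 1)))

  # {0.1..1.0}: union of kept intervals spans [0,1] after clamping
  fit <- suppressWarnings(divfit(qmat1(seq(0.1, 1, 0.1)), gamma = 0.2,
                                 beta = 1, transformed = TRUE))
  expect_equal(unname(fit$intervals["g1", ]), c(0, 1))

  set.seed(413)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    v <- stats::runif(n)
    gamma <- stats::runif(1, 0.05, 0.6)
    beta <- sample(c(1, stats::runif(1, 0.7, 1)), 1)
    fit <- suppressWarnings(divfit(qmat1(v), gamma = gamma, beta = beta,
                                   transformed = TRUE))
    expect_equal(unname(fit$intervals["g1", ]),
                 unname(oracle_interval(v, max(1, floor(n * gamma)), beta)),
                 tolerance = 1e-12)
  }
})

test_that("univariate model agrees with the |S|=1 multivariate support", {
  # the single interval must contain the union of kept 1-D spheres, and
  # every point outside the interval is outside every kept sphere
  set.seed(414)
  for (rep in 1:10) {
    v <- stats::runif(15)
    uni <- suppressWarnings(divfit(qmat1(v), gamma = 0.2, beta = 0.9,
                                   transformed = TRUE))
    s <- suppressWarnings(fit_support_for_set(qmat1(v), "g1", gamma = 0.2,
                                              beta = 0.9,
                                              transformed = TRUE))
    lo <- uni$intervals["g1", "lower"]; hi <- uni$intervals["g1", "upper"]
    for (p in seq(0, 1, by = 0.01)) {
      if (code_point(s, p) == 0L)
        expect_true(p >= lo && p <= hi)   # interval covers the union
    }
  }
})

test_that("beta trimming keeps spheres at or below the beta-quantile radius", {
  set.seed(415)
  Q <- rand_quantile_matrix(3, 20)
  s <- fit_support_for_set(Q, rownames(Q), gamma = 0.2, beta = 0.8,
                           transformed = TRUE)
  rbar <- stats::quantile(s$radii, 0.8, names = FALSE)
  expect_equal(unname(s$kept), unname(s$radii <= rbar))
  expect_true(any(s$kept))
  expect_false(all(s$kept))
})

test_that("achieved alpha is zero under beta = 1 and matches re-coding", {
  set.seed(416)
  x <- rand_omics(30, 25)
  fit <- divfit(x, gamma = 0.1, beta = 1)
  expect_equal(fit$achieved_alpha, 0)
  sets <- list(A = rownames(x)[1:4], B = rownames(x)[5:6])
  mfit <- divfit(x, type = "multivariate", sets = sets, gamma = 0.1, beta = 1)
  expect_equal(mfit$achieved_alpha, 0)

  # with trimming, the stored alpha equals coding the baseline via predict
  fit <- divfit(x, gamma = 0.1, beta = 0.9)
  expect_equal(baseline_alpha(fit, x), fit$achieved_alpha)
  mfit <- divfit(x, type = "multivariate", sets = sets, gamma = 0.1,
                 beta = 0.9)
  expect_equal(baseline_alpha(mfit, x), mfit$achieved_alpha)
})

test_that("gamma and beta act monotonically on the baseline alpha", {
  # note: with beta < 1 the trimmed-sphere set is decided by the *ranking*
  # of radii, which changes with the neighbourhood size, so supports at
  # different gamma need not nest and alpha-monotonicity in gamma is only
  # guaranteed without trimming (beta = 1)
  set.seed(417)
  for (rep in 1:6) {
    x <- rand_omics(25, sample(20:30, 1), zero_frac = 0.2)
    alphas <- vapply(c(0.05, 0.1, 0.2, 0.4),
                     function(g) divfit(x, gamma = g,
                                        beta = 1)$achieved_alpha, 0)
    expect_true(all(diff(alphas) <= 1e-12))
    betas <- vapply(c(0.7, 0.85, 1),
                    function(b) divfit(x, gamma = 0.1,
                                       beta = b)$achieved_alpha, 0)
    expect_true(all(diff(betas) <= 1e-12))
    # radii themselves grow with gamma
    Q <- quantile_transform(x)
    s1 <- fit_support_for_set(Q, rownames(Q)[1:3], gamma = 0.1, beta = 1,
                              transformed = TRUE)
    s2 <- fit_support_for_set(Q, rownames(Q)[1:3], gamma = 0.3, beta = 1,
                              transformed = TRUE)
    expect_true(all(s2$radii >= s1$radii - 1e-12))
  }
})

test_that("gamma search returns the smallest candidate meeting the budget", {
  set.seed(418)
  x <- rand_omics(40, 30, zero_frac = 0.2)
  res <- select_gamma(x, alpha_threshold = 0.01, beta = 0.9)
  expect_s3_class(res, "gamma_search")
  if (res$converged) {
    a <- res$achieved_alpha_per_candidate
    expect_lte(a[[as.character(res$selected_gamma)]], 0.01)
    earlier <- a[as.numeric(names(a)) < res$selected_gamma]
    expect_true(all(earlier > 0.01))
    # exhaustive check: no smaller candidate would have qualified
    for (g in res$candidate_gammas[res$candidate_gammas <
                                   res$selected_gamma]) {
      expect_gt(divfit(x, gamma = g, beta = 0.9)$achieved_alpha, 0.01)
    }
  }
  # beta = 1 makes the very first candidate qualify with alpha 0
  res1 <- suppressWarnings(select_gamma(x, beta = 1))
  expect_true(res1$converged)
  expect_equal(res1$selected_gamma, default_gamma_candidates()[1])
  expect_equal(unname(res1$achieved_alpha_per_candidate[1]), 0)
})

test_that("gamma search reports non-convergence instead of failing", {
  # an impossibly small budget cannot be met once trimming forces alpha > 0
  set.seed(419)
  x <- rand_omics(20, 25, zero_frac = 0)
  res <- select_gamma(x, candidates = c(0.05, 0.1), alpha_threshold = 1e-6,
                      beta = 0.8)
  expect_false(res$converged)
  expect_equal(res$selected_gamma, 0.1)
  expect_length(res$achieved_alpha_per_candidate, 2L)
  expect_warning(divfit(x, alpha = 1e-6, beta = 0.8,
                        gamma_candidates = c(0.05, 0.1)),
                 "no candidate gamma")
  expect_error(select_gamma(x, candidates = numeric(0)), "empty")
})

test_that("fit validation catches bad cohorts and parameters", {
  x <- rand_omics(10, 1)
  expect_error(divfit(x), "at least 2 samples")
  expect_warning(divfit(rand_omics(10, 5), gamma = 0.5, beta = 1),
                 "at least 20")
  x <- rand_omics(10, 25)
  expect_error(divfit(x, gamma = 1.5), "gamma")
  expect_error(divfit(x, beta = 0), "beta")
  expect_error(divfit(x, type = "multivariate"), "sets")
  expect_warning(divfit(x, gamma = 0.02, beta = 1), "clamping l to 1")
})

test_that("unresolvable set members are dropped and empty sets skipped", {
  set.seed(420)
  x <- rand_omics(20, 25)
  sets <- list(ok = rownames(x)[1:3],
               partial = c(rownames(x)[4], "missing1"),
               gone = c("missing2", "missing3"))
  expect_warning(expect_warning(
    fit <- divfit(x, type = "multivariate", sets = sets, gamma = 0.2),
    "dropped 3 set member"), "skipped 1 set")
  expect_named(fit$support, c("ok", "partial"))
  expect_equal(fit$support$partial$members, rownames(x)[4])
})

test_that("model JSON serialization round-trips predictions exactly", {
  set.seed(421)
  x <- rand_omics(20, 25)
  cases <- rand_omics(20, 10)
  rownames(cases) <- rownames(x)
  path <- withr::local_tempfile(fileext = ".json")

  fit <- divfit(x, gamma = 0.1, beta = 0.9)
  write_divergence_model(fit, path)
  back <- read_divergence_model(path)
  expect_equal(back$intervals, fit$intervals)
  expect_equal(predict(back, cases), predict(fit, cases))

  sets <- list(A = rownames(x)[1:4], B = rownames(x)[7:9])
  mfit <- divfit(x, type = "multivariate", sets = sets, gamma = 0.2,
                 beta = 0.9)
  write_divergence_model(mfit, path)
  mback <- read_divergence_model(path)
  expect_equal(predict(mback, cases), predict(mfit, cases))
  expect_equal(mback$gamma, mfit$gamma)
})
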