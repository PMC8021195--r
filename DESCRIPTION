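Package: divcode
Title: Digitized Divergence Coding of Omics Profiles Against a Baseline Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms high-dimensional omics profiles (RNA-seq expression,
    methylation beta values and similar modalities) into simple digitized codes
    describing how each feature of a sample diverges from a baseline (reference)
    cohort. Each sample is rank-transformed to quantile scale with zeros
    preserved; the baseline support is estimated from k-nearest-neighbour
    spheres with outlier trimming, reduced to a single interval per feature in
    the univariate case; case samples are then coded ternary (-1/0/1, below /
    within / above the baseline interval) or binary (0/1, inside / outside a
    multivariate gene-set support). Downstream tools cover divergence
    probabilities, per-sample divergence counts, chi-squared screening for
    differential divergence between phenotypes, co-divergence across omics
    modalities, CpG clustering with permutation-based region p-values, and a
    synthetic-cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
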