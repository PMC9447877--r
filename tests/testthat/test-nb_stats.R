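test_that("size factors: symmetry, worked example, and failure mode", {
  m <- matrix(c(5, 7, 9, 5, 7, 9), nrow = 3,
              dimnames = list(paste0("h", 1:3), c("s1", "s2")))
  expect_equal(unname(compute_size_factors(m)), c(1, 1))

  # hand median-of-ratios: columns in 1:2 ratio, geometric-mean-1 convention
  m2 <- matrix(c(2, 6, 10, 4, 12, 20), nrow = 3,
               dimnames = list(paste0("h", 1:3), c("s1", "s2")))
  expect_equal(unname(compute_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # a zero in every row leaves no usable hairpin
  m3 <- matrix(c(0, 5, 5, 0), nrow = 2,
               dimnames = list(c("h1", "h2"), c("s1", "s2")))
  expect_error(compute_size_factors(m3), "no hairpin has positive counts")
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(101)
  for (trial in 1:200) {
    m <- matrix(rpois(40, 20), nrow = 10,
                dimnames = list(paste0("h", 1:10), paste0("s", 1:4)))
    m[1, ] <- m[1, ] + 1L  # guarantee one all-positive row
    expect_equal(unname(compute_size_factors(m)), oracle_size_factors(m),
                 tolerance = 1e-12)
  }
})

test_that("size factors are sample-permutation equivariant and row-order invariant", {
  set.seed(7)
  m <- matrix(rpois(60, 50) + 1L, nrow = 10,
              dimnames = list(paste0("h", 1:10), paste0("s", 1:6)))
  sf <- compute_size_factors(m)
  perm <- sample(6)
  expect_equal(compute_size_factors(m[, perm]), sf[perm])
  expect_equal(unname(compute_size_factors(m[sample(10), ])), unname(sf))
})

test_that("size factors agree with DESeq2's median-of-ratios estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(21)
  # odd row count: the raw-ratio median and DESeq2's log-scale median pick
  # the same middle element, so the two estimators must agree exactly
  m <- matrix(rnbinom(501 * 4, mu = 300, size = 10), nrow = 501,
              dimnames = list(paste0("h", 1:501), paste0("s", 1:4)))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))  # same geometric-mean-1 convention
  expect_equal(unname(compute_size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("normalization divides by size factors", {
  m <- matrix(c(4, 8, 2, 6), nrow = 2, dimnames = list(c("h1", "h2"), c("s1", "s2")))
  expect_equal(normalize_counts(m, c(s1 = 1, s2 = 1)), m)
  halved <- normalize_counts(m, c(s1 = 1, s2 = 2))
  expect_equal(halved[, "s2"], m[, "s2"] / 2)
  expect_equal(halved[, "s1"], m[, "s1"])
  expect_error(normalize_counts(m, c(sX = 1, sY = 2)), "do not match")
  expect_error(normalize_counts(m, 1), "length")
})

test_that("dispersion estimates vanish on Poisson data and recover planted alpha", {
  set.seed(31)
  n <- 200L
  m <- matrix(rpois(500 * n, 500), nrow = 500,
              dimnames = list(paste0("h", 1:500), paste0("s", 1:n)))
  groups <- rep(c("A", "B"), each = n / 2)
  sf <- compute_size_factors(m)
  d <- estimate_dispersions(m, groups, sf)
  expect_true(all(d$alpha >= 0))
  expect_lt(median(d$alpha), 0.02)

  set.seed(32)
  m2 <- matrix(rnbinom(500 * n, mu = 500, size = 1 / 0.1), nrow = 500,
               dimnames = list(paste0("h", 1:500), paste0("s", 1:n)))
  d2 <- estimate_dispersions(m2, groups, compute_size_factors(m2))
  expect_gt(median(d2$alpha), 0.05)
  expect_lt(median(d2$alpha), 0.2)

  expect_error(estimate_dispersions(m[, 1, drop = FALSE], "A", 1), "at least 2 samples")
})

test_that("dispersion estimation falls back to blind pooling with single-sample groups", {
  set.seed(33)
  m <- matrix(rnbinom(200 * 4, mu = 300, size = 20), nrow = 200,
              dimnames = list(paste0("h", 1:200), paste0("s", 1:4)))
  d <- estimate_dispersions(m, c("t0", "untreated", "treated", "treated"),
                            compute_size_factors(m))
  expect_identical(d$method, "blind")
  expect_true(all(is.finite(d$alpha)) && all(d$alpha >= 0))
})

test_that("contrast on identical arms yields exactly zero fold changes", {
  manifest <- tiny_manifest(genes = c("A", "B"), hairpins_per_gene = 2L)
  sheet <- tiny_sheet(n_rep = 2L)
  base <- matrix(rpois(4 * 2, 400) + 1L, 4, 2)
  counts <- cbind(base, base, base)  # every arm identical
  dimnames(counts) <- list(manifest$hairpin_id, sheet$sample_id)
  counts <- validate_count_matrix(counts, manifest, sheet)
  sf <- compute_size_factors(counts)
  d <- estimate_dispersions(counts, sheet$arm, sf)
  res <- test_contrast(counts, sheet, manifest, sf, d, "untreated", "treated")
  expect_equal(res$log2fc, rep(0, 4))
  expect_identical(unique(res$contrast), "treated_vs_untreated")
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
})

test_that("contrast is antisymmetric in arms and inert on all-zero hairpins", {
  set.seed(41)
  manifest <- tiny_manifest(genes = sprintf("G%02d", 1:10), hairpins_per_gene = 3L)
  sheet <- tiny_sheet(n_rep = 3L)
  counts <- matrix(rnbinom(30 * 9, mu = 500, size = 20), 30, 9,
                   dimnames = list(manifest$hairpin_id, sheet$sample_id))
  counts[5, ] <- 0L  # an undetected hairpin
  counts <- validate_count_matrix(counts, manifest, sheet)
  sf <- compute_size_factors(counts)
  d <- estimate_dispersions(counts, sheet$arm, sf)
  fwd <- test_contrast(counts, sheet, manifest, sf, d, "untreated", "treated")
  rev <- test_contrast(counts, sheet, manifest, sf, d, "treated", "untreated")
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$pvalue, rev$pvalue, tolerance = 1e-12)

  zero_row <- fwd[fwd$baseMeanA == 0 & fwd$log2fc == 0, ]
  expect_equal(zero_row$pvalue, 1)
  expect_equal(zero_row$fdr, 1)

  expect_error(test_contrast(counts, sheet[sheet$arm != "treated", ], manifest,
                             sf, d, "untreated", "treated"), "no samples")
})

test_that("a planted 4-fold depletion is estimated near log2fc = -2", {
  # one gene depleted 4-fold in the treated arm at baseMean ~ 1000
  medians <- vapply(1:5, function(s) {
    p <- screen_sim_params(n_kinase_genes = 50L, n_kinase_related = 0L,
                           n_essential_control_hairpins = 0L,
                           n_nonessential_control_hairpins = 0L,
                           dispersion = 0.01, hairpin_effect_sd = 0,
                           inert_fraction = 0, depth_factor_sd = 0,
                           planted_common_hits = "KIN0001", seed = 400L + s)
    manifest <- build_default_manifest(p)
    sim <- simulate_screen(manifest, p, "CL1")
    sf <- compute_size_factors(sim$counts)
    d <- estimate_dispersions(sim$counts, sim$sheet$arm, sf)
    res <- test_contrast(sim$counts, sim$sheet, manifest, sf, d, "untreated", "treated")
    median(res$log2fc[res$gene_symbol == "KIN0001"])
  }, numeric(1L))
  expect_gt(median(medians), -2.3)
  expect_lt(median(medians), -1.7)
})

test_that("BH adjustment matches hand example, edge cases, and brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "within \\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "within \\[0, 1\\]")

  set.seed(51)
  for (trial in 1:50) {
    p <- runif(sample(50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone in the p-value ranking", {
  set.seed(52)
  p <- runif(100)
  fdr <- bh_adjust(p)
  expect_true(all(diff(fdr[order(p)]) >= -1e-15))
  expect_true(all(fdr >= p - 1e-15))
})
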