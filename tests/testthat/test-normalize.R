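test_that("CPM matches direct arithmetic and conserves 1e6 per column", {
  counts <- rbind(A = c(10, 0), B = c(5, 5), C = c(0, 1))
  colnames(counts) <- c("s1", "s2")
  m <- count_matrix(counts, "c")
  expect_identical(unname(m$library_sizes), c(15, 6))
  cpm <- compute_cpm(m)
  expect_equal(cpm["A", "s1"], 10 / 15 * 1e6)
  expect_equal(cpm["C", "s1"], 0)
  expect_equal(cpm["B", "s2"], 5 / 6 * 1e6)

  m2 <- random_counts(11, n_genes = 4, n_samples = 3)
  cpm2 <- compute_cpm(m2)
  hand <- m2$counts
  for (k in 1:3) hand[, k] <- m2$counts[, k] / sum(m2$counts[, k]) * 1e6
  expect_equal(unclass(cpm2), hand, ignore_attr = TRUE)
  expect_equal(unname(colSums(cpm2)), rep(1e6, 3), tolerance = 1e-6)

  zero <- count_matrix(matrix(c(1L, 0L), 2, 2,
                              dimnames = list(c("A", "B"), c("ok", "empty"))), "c")
  zero$counts[, "empty"] <- 0L
  zero$library_sizes <- colSums(zero$counts)
  expect_error(compute_cpm(zero), "empty")
})

test_that("both low-expression filter dialects match a brute-force scan", {
  m <- random_counts(5, n_genes = 50, n_samples = 10, mu = 2, size = 0.5)
  cpm <- unclass(compute_cpm(m))

  for (cfg in list(filter_config("nonzero_fraction", sample_fraction = 0.70),
                   filter_config("cpm_gt1", cpm_threshold = 1,
                                 sample_fraction = 0.70))) {
    kept <- rownames(filter_low_expression(m, cfg)$counts)
    brute <- character(0)
    for (g in rownames(cpm)) {
      if (cfg$mode == "nonzero_fraction") {
        if (!(mean(cpm[g, ] == 0) > cfg$sample_fraction)) brute <- c(brute, g)
      } else {
        if (mean(cpm[g, ] > cfg$cpm_threshold) >= cfg$sample_fraction)
          brute <- c(brute, g)
      }
    }
    expect_identical(kept, brute)
  }
})

test_that("filter boundary cases follow the stated rules", {
  # CPM zero in 8/10 samples (0.8 > 0.7) -> discarded under nonzero_fraction
  counts <- rbind(ZEROISH = c(rep(0L, 8), 5L, 5L),
                  STEADY = rep(10L, 10))
  colnames(counts) <- sprintf("s%02d", 1:10)
  m <- count_matrix(counts, "c")
  kept <- rownames(filter_low_expression(m, filter_config("nonzero_fraction"))$counts)
  expect_identical(kept, "STEADY")
  # CPM > 1 everywhere -> kept under cpm_gt1
  kept2 <- rownames(filter_low_expression(m, filter_config("cpm_gt1"))$counts)
  expect_identical(kept2, "STEADY")
  expect_error(
    filter_low_expression(m, filter_config("cpm_gt1", cpm_threshold = 1e9)),
    "every gene")
})

test_that("raising the cpm_gt1 thresholds never grows the kept gene set", {
  m <- random_counts(6, n_genes = 40, n_samples = 8, mu = 10, size = 0.8)
  kept <- function(thr, frac)
    rownames(filter_low_expression(
      m, filter_config("cpm_gt1", cpm_threshold = thr,
                       sample_fraction = frac))$counts)
  base <- kept(1, 0.5)
  expect_true(all(kept(5, 0.5) %in% base))
  expect_true(all(kept(1, 0.8) %in% base))
  expect_true(all(kept(5, 0.8) %in% kept(5, 0.5)))
})

test_that("TMM factors are exactly 1 for identical and scalar-scaled columns", {
  a <- c(50L, 10L, 200L, 5L, 80L, 30L, 11L, 95L)
  cols <- cbind(s1 = a, s2 = a, s3 = 3L * a)
  rownames(cols) <- sprintf("G%d", 1:8)
  m <- count_matrix(cols, "c")
  nf <- tmm_factors(m)
  expect_equal(nf$tmm_factor, rep(1, 3), tolerance = 1e-12)
  expect_equal(nf$effective_library_size, nf$library_size, tolerance = 1e-9)
})

test_that("TMM matches the brute-force transcription on 100 seeded matrices", {
  worst <- 0
  for (seed in 1:100) {
    set.seed(seed)
    ng <- sample(10:30, 1); ns <- sample(2:6, 1)
    m <- random_counts(seed * 1000L, n_genes = ng, n_samples = ns,
                       mu = sample(c(20, 50, 200), 1), size = 0.7)
    nf <- tmm_factors(m)
    expect_equal(nf$tmm_factor, oracle_tmm(m$counts), tolerance = 1e-10)
    worst <- max(worst, max(abs(nf$tmm_factor - oracle_tmm(m$counts))))
  }
  expect_lt(worst, 1e-10)
})

test_that("TMM respects unweighted mode and the geometric-mean constraint", {
  m <- random_counts(77, n_genes = 25, n_samples = 5)
  cfg <- tmm_config(weighting = FALSE)
  nf <- tmm_factors(m, cfg)
  expect_equal(nf$tmm_factor,
               oracle_tmm(m$counts, weighting = FALSE), tolerance = 1e-10)
  expect_equal(exp(mean(log(nf$tmm_factor))), 1, tolerance = 1e-10)
  expect_true(all(nf$effective_library_size > 0))
})

test_that("TMM is invariant to gene-row permutation", {
  m <- random_counts(42, n_genes = 30, n_samples = 4)
  set.seed(1); perm <- sample(nrow(m$counts))
  mp <- count_matrix(m$counts[perm, ], "c")
  expect_equal(tmm_factors(m)$tmm_factor, tmm_factors(mp)$tmm_factor,
               tolerance = 1e-12)
})

test_that("TMM agrees with the established edgeR implementation", {
  # tie-free counts so rank-based trimming is unambiguous
  set.seed(314)
  counts <- matrix(rpois(30 * 5, lambda = exp(runif(150, 2, 7))), 30, 5,
                   dimnames = list(sprintf("G%02d", 1:30), sprintf("S%d", 1:5)))
  m <- count_matrix(counts, "c")
  ours <- tmm_factors(m)$tmm_factor
  theirs <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(ours, unname(theirs), tolerance = 1e-8)
})

test_that("RPKM matches hand arithmetic and scales as expected", {
  ann <- suppressMessages(gene_annotation(data.frame(
    symbol = c("A", "B"), length_bp = c(1000L, 2000L),
    is_gpcr = c(TRUE, FALSE))))
  counts <- matrix(c(10L, 20L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  m <- count_matrix(counts, "c")
  nf <- data.frame(sample_id = "s1", library_size = 30,
                   tmm_factor = 1, effective_library_size = 1e6)
  class(nf) <- c("norm_factors", "data.frame")
  r <- compute_rpkm(m, ann, nf)
  expect_equal(r["A", "s1"], 10)           # 10 * 1e9 / (1000 * 1e6)
  expect_equal(r["B", "s1"], 10)           # double counts, double length

  # homogeneity: doubling counts doubles RPKM at fixed factors; doubling
  # length or effective library size halves it
  m2 <- count_matrix(counts * 2L, "c")
  expect_equal(unclass(compute_rpkm(m2, ann, nf)),
               unclass(r) * 2, ignore_attr = TRUE)
  nf2 <- nf; nf2$effective_library_size <- 2e6
  expect_equal(unclass(compute_rpkm(m, ann, nf2)),
               unclass(r) / 2, ignore_attr = TRUE)

  # 5 x 3 worked example with non-unit factors
  m5 <- random_counts(9, n_genes = 5, n_samples = 3)
  ann5 <- suppressMessages(gene_annotation(data.frame(
    symbol = rownames(m5$counts), length_bp = c(500L, 1000L, 1500L, 2000L, 2500L),
    is_gpcr = FALSE)))
  nf5 <- tmm_factors(m5)
  r5 <- compute_rpkm(m5, ann5, nf5)
  for (g in 1:5) for (k in 1:3) {
    expect_equal(r5[g, k],
                 m5$counts[g, k] * 1e9 /
                   (ann5$length_bp[g] * nf5$effective_library_size[k]))
  }
  expect_error(compute_rpkm(m5, ann, nf5), "length missing")
})

test_that("distribution summaries report log-scale quantiles per subset", {
  e <- expr_matrix(matrix(7, 3, 4, dimnames = list(c("A", "B", "C"), NULL)),
                   unit = "RPKM")
  s <- distribution_summary(e, c("A", "B"))
  expect_true(all(s$quantiles_all == log2(8)))
  expect_true(all(s$quantiles_subset == log2(8)))

  m <- random_counts(3, n_genes = 30, n_samples = 5)
  e2 <- compute_cpm(m)
  s2 <- distribution_summary(e2, rownames(e2))
  expect_equal(s2$quantiles_all, s2$quantiles_subset)
  expect_warning(distribution_summary(e2, "NOT_A_GENE"), "empty")
})
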