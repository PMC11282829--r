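test_that("expression calls follow the level-and-fraction rule", {
  v <- rbind(HIT  = c(rep(50, 4), rep(10, 6)),   # 50% of ref in 4/10 samples
             LOW  = rep(39, 10),                 # just below the level cut
             EDGE = c(rep(40, 3), rep(0, 7)))    # exactly 30% of samples at 40%
  colnames(v) <- paste0("s", 1:10)
  pct <- expr_matrix(v, unit = "PCT_REF")
  called <- call_expressed(pct, c("HIT", "LOW", "EDGE"), selection_config())
  expect_identical(called, c("EDGE", "HIT"))   # >= comparisons: boundary passes
  expect_error(call_expressed(pct, "OTHER"), "no GPCR")
})

test_that("expression calls equal a brute-force double loop on random input", {
  pct <- random_pct(101, n_genes = 30, n_samples = 20, na_frac = 0.1)
  cfg <- selection_config(level_threshold_pct = 40,
                          within_cohort_fraction = 0.30)
  called <- call_expressed(pct, rownames(pct), cfg)
  brute <- character(0)
  for (g in rownames(pct)) {
    num <- 0; den <- 0
    for (s in colnames(pct)) {
      if (!is.na(pct[g, s])) {
        den <- den + 1
        if (pct[g, s] >= 40) num <- num + 1
      }
    }
    if (den > 0 && num / den >= 0.30) brute <- c(brute, g)
  }
  expect_identical(called, sort(brute))
})

test_that("cohort frequencies count memberships exactly", {
  freq <- cohort_frequency(list(c1 = "A", c2 = "A", c3 = c("A", "B")),
                           selection_config())
  expect_identical(freq$preselected, "A")
  expect_identical(unname(freq$frequency[c("A", "B")]), c(3L, 1L))

  # random sets versus brute-force membership counting
  set.seed(55)
  genes <- sprintf("G%02d", 1:50)
  sets <- lapply(1:100, function(i) sample(genes, sample(0:20, 1)))
  names(sets) <- sprintf("c%03d", 1:100)
  freq2 <- cohort_frequency(sets, selection_config(min_cohorts = 30))
  for (g in names(freq2$frequency)) {
    expect_identical(unname(freq2$frequency[g]),
                     sum(vapply(sets, function(s) g %in% s, logical(1))))
  }
  expect_identical(freq2$preselected,
                   sort(names(freq2$frequency)[freq2$frequency >= 30]))
})

test_that("healthy baseline stats respect tissue scope", {
  v <- matrix(seq_len(27), nrow = 3,
              dimnames = list(c("A", "B", "C"), sprintf("h%d", 1:9)))
  e <- expr_matrix(v, unit = "RPKM")
  meta <- data.frame(sample_id = sprintf("h%d", 1:9), cohort_id = "healthy",
                     condition = "healthy",
                     tissue = rep(c("peritoneal", "fallopian", "ovarian_surface"),
                                  each = 3))
  st <- healthy_reference_stats(e, meta, c("A", "B"),
                                selection_config(healthy_tissue_scope = "peritoneal_only"))
  expect_identical(attr(st, "n_healthy"), 3L)
  expect_equal(st$mean_healthy[st$gene == "A"], mean(v["A", 1:3]))
  expect_equal(st$sd_healthy[st$gene == "A"], sd(v["A", 1:3]))

  st9 <- healthy_reference_stats(e, meta, "A",
                                 selection_config(healthy_tissue_scope = "all_healthy"))
  expect_identical(attr(st9, "n_healthy"), 9L)

  # simple numbers: values (1,2,3) -> mean 2, sd 1
  e2 <- expr_matrix(matrix(c(1, 2, 3), 1, 3,
                           dimnames = list("A", c("h1", "h2", "h3"))), "RPKM")
  m2 <- meta[1:3, ]
  st2 <- healthy_reference_stats(e2, m2, "A", selection_config())
  expect_equal(st2$mean_healthy, 2)
  expect_equal(st2$sd_healthy, 1)

  # genes absent from the healthy matrix are "not expressed"
  st3 <- healthy_reference_stats(e, meta, c("A", "GONE"), selection_config())
  expect_equal(st3$mean_healthy[st3$gene == "GONE"], 0)
  expect_error(healthy_reference_stats(e, meta[1, ], "A", selection_config()),
               ">= 2")
})

test_that("the healthy overexpression filter retains by pooled pass fraction", {
  st <- data.frame(gene = c("KEEP", "DROP"), mean_healthy = c(1, 1),
                   sd_healthy = c(0.5, 0.5))
  attr(st, "n_healthy") <- 3L; attr(st, "scale") <- "RPKM"
  class(st) <- c("healthy_stats", "data.frame")
  # cutoff = 1 + 2 * 0.5 = 2; KEEP >= 2 in 70%, DROP in 60%
  v <- rbind(KEEP = c(rep(2, 7), rep(0, 3)),
             DROP = c(rep(5, 6), rep(1, 4)))
  colnames(v) <- paste0("s", 1:10)
  pooled <- expr_matrix(v, unit = "RPKM")
  res <- healthy_overexpression_filter(pooled, st, c("KEEP", "DROP"),
                                       selection_config())
  expect_identical(res$final_targets, "KEEP")
  expect_equal(unname(res$pass_fraction), c(0.7, 0.6))
  expect_equal(unname(res$cutoff), c(2, 2))
  expect_error(healthy_overexpression_filter(pooled, st, character(0)),
               "empty")
})

test_that("a planted 13-of-45 pooled design is recovered exactly", {
  # 45 candidates x 151 pooled samples; 13 planted genes exceed their healthy
  # cutoff in 70% of samples, the rest in only 30%
  set.seed(77)
  genes <- sprintf("CAND%02d", 1:45)
  planted <- sort(sample(genes, 13))
  st <- data.frame(gene = genes, mean_healthy = runif(45, 0.5, 2),
                   sd_healthy = runif(45, 0.1, 0.6))
  attr(st, "n_healthy") <- 3L; attr(st, "scale") <- "RPKM"
  class(st) <- c("healthy_stats", "data.frame")
  cutoff <- st$mean_healthy + 2 * st$sd_healthy
  n <- 151
  v <- matrix(0, 45, n, dimnames = list(genes, sprintf("s%03d", 1:n)))
  for (i in seq_len(45)) {
    frac <- if (genes[i] %in% planted) 0.70 else 0.30
    hot <- sample(n, round(frac * n))
    v[i, hot] <- cutoff[i] * 1.5
    v[i, -hot] <- cutoff[i] * 0.5
  }
  pooled <- expr_matrix(v, unit = "RPKM")
  res <- healthy_overexpression_filter(pooled, st, genes, selection_config())
  expect_identical(res$final_targets, planted)
})

test_that("co-expression fractions match brute-force counting and are bounded", {
  pct <- random_pct(202, n_genes = 2, n_samples = 100, na_frac = 0.05)
  rownames(pct) <- c("A", "B")
  cfg <- selection_config()
  res <- coexpression_fraction(pct, "A", "B", cfg)
  na_ <- 0; nb <- 0; da <- 0; db <- 0; nboth <- 0; dboth <- 0
  for (s in 1:100) {
    a <- pct["A", s]; b <- pct["B", s]
    if (!is.na(a)) { da <- da + 1; if (a >= 40) na_ <- na_ + 1 }
    if (!is.na(b)) { db <- db + 1; if (b >= 40) nb <- nb + 1 }
    if (!is.na(a) && !is.na(b)) {
      dboth <- dboth + 1
      if (a >= 40 && b >= 40) nboth <- nboth + 1
    }
  }
  expect_equal(res$fraction_a, na_ / da)
  expect_equal(res$fraction_b, nb / db)
  expect_equal(res$fraction_both, nboth / dboth)
  expect_lte(res$fraction_both, min(res$fraction_a, res$fraction_b) + 1e-12)

  # disjoint and identical patterns
  v <- rbind(A = c(100, 100, 0, 0), B = c(0, 0, 100, 100))
  colnames(v) <- paste0("s", 1:4)
  expect_equal(coexpression_fraction(expr_matrix(v, "PCT_REF"), "A", "B",
                                     cfg)$fraction_both, 0)
  v2 <- rbind(A = c(100, 0, 100, 0), B = c(100, 0, 100, 0))
  colnames(v2) <- paste0("s", 1:4)
  r2 <- coexpression_fraction(expr_matrix(v2, "PCT_REF"), "A", "B", cfg)
  expect_equal(r2$fraction_both, r2$fraction_a)
  expect_error(coexpression_fraction(expr_matrix(v2, "PCT_REF"), "A", "NOPE"),
               "NOPE")
})

test_that("tightening any cascade threshold never enlarges the output set", {
  pct <- random_pct(303, n_genes = 25, n_samples = 40, na_frac = 0.05)
  genes <- rownames(pct)

  # level threshold and within-cohort fraction on expression calls
  for (pair in list(c(30, 50), c(40, 60))) {
    lo <- call_expressed(pct, genes, selection_config(level_threshold_pct = pair[1]))
    hi <- call_expressed(pct, genes, selection_config(level_threshold_pct = pair[2]))
    expect_true(all(hi %in% lo))
  }
  lo <- call_expressed(pct, genes, selection_config(within_cohort_fraction = 0.2))
  hi <- call_expressed(pct, genes, selection_config(within_cohort_fraction = 0.5))
  expect_true(all(hi %in% lo))

  # min_cohorts on the frequency stage
  set.seed(9)
  sets <- lapply(1:6, function(i) sample(genes, 12))
  names(sets) <- paste0("c", 1:6)
  for (k in 1:5) {
    a <- cohort_frequency(sets, selection_config(min_cohorts = k))$preselected
    b <- cohort_frequency(sets, selection_config(min_cohorts = k + 1))$preselected
    expect_true(all(b %in% a))
  }

  # sd multiplier and pooled fraction on the healthy filter
  st <- data.frame(gene = genes, mean_healthy = runif(25, 0.5, 2),
                   sd_healthy = runif(25, 0.1, 1))
  attr(st, "n_healthy") <- 3L; attr(st, "scale") <- "PCT_REF"
  class(st) <- c("healthy_stats", "data.frame")
  for (mult in list(c(1, 2), c(2, 3))) {
    a <- healthy_overexpression_filter(pct, st, genes,
           selection_config(sd_multiplier = mult[1]))$final_targets
    b <- healthy_overexpression_filter(pct, st, genes,
           selection_config(sd_multiplier = mult[2]))$final_targets
    expect_true(all(b %in% a))
  }
  a <- healthy_overexpression_filter(pct, st, genes,
         selection_config(pooled_fraction = 0.5))$final_targets
  b <- healthy_overexpression_filter(pct, st, genes,
         selection_config(pooled_fraction = 0.8))$final_targets
  expect_true(all(b %in% a))
})

test_that("report construction enforces cascade containment", {
  sets <- list(c1 = c("A", "B"), c2 = "A")
  freq <- cohort_frequency(sets, selection_config(min_cohorts = 2))
  expect_error(selection_report(sets, freq$frequency, "C", "C",
                                c(C = 1)), "union")
  expect_error(selection_report(sets, freq$frequency, "A", "B",
                                c(B = 1)), "preselected")
  rep <- selection_report(sets, freq$frequency, "A", "A", c(A = 1))
  expect_s3_class(rep, "selection_report")
})
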