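# Independent brute-force oracles, written as literal transcriptions of the
# definitions. They deliberately share no code with the package internals.

# TMM: doubly trimmed, variance-weighted mean of per-gene log2 ratios versus
# the reference sample, plain loops throughout.
oracle_tmm <- function(counts, logratio_trim = 0.30, abs_intensity_trim = 0.05,
                       weighting = TRUE) {
  N <- colSums(counts)
  n <- ncol(counts)
  # reference: 75th-percentile CPM closest to the mean 75th percentile
  q75 <- numeric(n)
  for (k in seq_len(n)) {
    q75[k] <- quantile(counts[, k] / N[k] * 1e6, probs = 0.75, names = FALSE)
  }
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(n)
  for (k in seq_len(n)) {
    if (k == ref) { f[k] <- 1; next }
    M <- c(); A <- c(); w <- c()
    for (g in seq_len(nrow(counts))) {
      yk <- counts[g, k]; yr <- counts[g, ref]
      if (yk > 0 && yr > 0) {
        pk <- yk / N[k]; pr <- yr / N[ref]
        M <- c(M, log2(pk / pr))
        A <- c(A, 0.5 * log2(pk * pr))
        w <- c(w, if (weighting)
          1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
          else 1)
      }
    }
    ng <- length(M)
    loM <- floor(ng * logratio_trim) + 1; hiM <- ng + 1 - loM
    loA <- floor(ng * abs_intensity_trim) + 1; hiA <- ng + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep <- which(rM >= loM & rM <= hiM & rA >= loA & rA <= hiA)
    if (!length(keep)) keep <- seq_len(ng)
    f[k] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# Average-linkage agglomeration by direct search over the current partition.
# Returns the ordered sequence of merge heights.
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- mean(d[clusters[[i]], clusters[[j]]])
          if (h < best_h) { best_h <- h; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Random count matrix with a fixed seed.
random_counts <- function(seed, n_genes = 20, n_samples = 4, mu = 50,
                          size = 3, cohort = "test") {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  count_matrix(m, cohort)
}

# Small percent-of-reference matrix with optional NA cells.
random_pct <- function(seed, n_genes = 10, n_samples = 8, na_frac = 0) {
  set.seed(seed)
  v <- matrix(runif(n_genes * n_samples, 0, 200), n_genes, n_samples,
              dimnames = list(sprintf("R%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  if (na_frac > 0) v[runif(length(v)) < na_frac] <- NA
  expr_matrix(v, unit = "PCT_REF")
}

table3_path <- function() {
  system.file("extdata", "frequent_gpcrs.tsv", package = "gpcrhunt",
              mustWork = TRUE)
}

# Encode the reference frequency table as per-cohort membership sets:
# a gene listed with n_datasets = n is placed in the first n of five sets.
table3_sets <- function() {
  tab <- read.delim(table3_path())
  sets <- lapply(1:5, function(k) tab$gene[tab$n_datasets >= k])
  names(sets) <- paste0("DS", 1:5)
  sets
}
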