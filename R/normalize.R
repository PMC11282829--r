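#' Low-expression filter configuration
#'
#' Two dialects of the pre-normalization filter are supported:
#' `nonzero_fraction` discards genes whose CPM equals zero in more than
#' `sample_fraction` of a cohort's samples (the default); `cpm_gt1` keeps
#' genes with CPM above `cpm_threshold` in at least `sample_fraction` of
#' samples.
#'
#' @param mode `"nonzero_fraction"` or `"cpm_gt1"`.
#' @param cpm_threshold CPM cut used by the `cpm_gt1` mode (default 1).
#' @param sample_fraction fraction of samples in (0, 1] (default 0.70).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(mode = c("nonzero_fraction", "cpm_gt1"),
                          cpm_threshold = 1, sample_fraction = 0.70) {
  mode <- match.arg(mode)
  stopifnot(cpm_threshold >= 0,
            sample_fraction > 0, sample_fraction <= 1)
  structure(list(mode = mode, cpm_threshold = cpm_threshold,
                 sample_fraction = sample_fraction),
            class = "filter_config")
}

#' TMM configuration
#'
#' Trim fractions and weighting follow the standard trimmed-mean-of-M-values
#' definition: 30% two-sided trim on log-ratios (M), 5% on average log
#' intensity (A), inverse-asymptotic-variance weights.
#'
#' @param logratio_trim two-sided trim fraction on M, in \[0, 0.5).
#' @param abs_intensity_trim two-sided trim fraction on A, in \[0, 0.5).
#' @param weighting use inverse-variance weights (default `TRUE`).
#' @return A list of class `tmm_config`.
#' @export
tmm_config <- function(logratio_trim = 0.30, abs_intensity_trim = 0.05,
                       weighting = TRUE) {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abs_intensity_trim >= 0, abs_intensity_trim < 0.5,
            is.logical(weighting))
  structure(list(logratio_trim = logratio_trim,
                 abs_intensity_trim = abs_intensity_trim,
                 weighting = weighting),
            class = "tmm_config")
}

#' Counts per million
#'
#' `value(g, k) = counts(g, k) / N_k * 1e6` with `N_k` the raw library size
#' (column sum). Each column of an unfiltered matrix therefore sums to 1e6.
#'
#' @param m a [count_matrix()].
#' @return An [expr_matrix()] with unit `"CPM"`.
#' @export
compute_cpm <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  zero <- m$library_sizes == 0
  if (any(zero))
    stop("zero library size for sample(s): ",
         paste(names(m$library_sizes)[zero], collapse = ", "))
  v <- sweep(m$counts, 2L, m$library_sizes, "/") * 1e6
  expr_matrix(v, unit = "CPM",
              provenance = paste0("cpm(", m$cohort_id, ")"))
}

#' Remove genes with no or very low expression
#'
#' @param m a [count_matrix()].
#' @param cfg a [filter_config()].
#' @return A [count_matrix()] restricted to the kept genes, original gene
#'   order and counts unmodified.
#' @export
filter_low_expression <- function(m, cfg = filter_config()) {
  stopifnot(inherits(m, "count_matrix"), inherits(cfg, "filter_config"))
  cpm <- unclass(compute_cpm(m))
  keep <- switch(cfg$mode,
    cpm_gt1 = rowMeans(cpm > cfg$cpm_threshold) >= cfg$sample_fraction,
    nonzero_fraction = rowMeans(cpm == 0) <= cfg$sample_fraction)
  if (!any(keep))
    stop("low-expression filter removed every gene; review cpm_threshold/sample_fraction")
  out <- m
  out$counts <- m$counts[keep, , drop = FALSE]
  out$library_sizes <- colSums(out$counts)
  out
}

#' TMM scaling factors
#'
#' Computes one trimmed-mean-of-M-values scaling factor per sample against a
#' data-selected reference sample (the sample whose 75th-percentile CPM is
#' closest to the mean 75th percentile). For sample k versus reference r, over
#' genes with positive counts in both, `M_g = log2((y_gk/N_k)/(y_gr/N_r))` and
#' `A_g = 0.5 * log2((y_gk/N_k) * (y_gr/N_r))`; the top and bottom
#' `logratio_trim` fraction by M and `abs_intensity_trim` fraction by A are
#' dropped (rank-based, ties broken by gene order) and
#' `f_k = 2^(weighted mean of surviving M)` with inverse-asymptotic-variance
#' weights. Factors are finally rescaled so their geometric mean is exactly 1.
#'
#' @param m a [count_matrix()] (typically after [filter_low_expression()]).
#' @param cfg a [tmm_config()].
#' @return A data.frame of class `norm_factors` with columns `sample_id`,
#'   `library_size`, `tmm_factor`, `effective_library_size`; the chosen
#'   reference sample is stored in attribute `reference_sample`.
#' @export
tmm_factors <- function(m, cfg = tmm_config()) {
  stopifnot(inherits(m, "count_matrix"), inherits(cfg, "tmm_config"))
  counts <- m$counts
  N <- m$library_sizes
  n <- ncol(counts)
  if (n < 2L) stop("TMM needs at least 2 samples")
  cpm <- sweep(counts, 2L, N, "/") * 1e6
  q75 <- apply(cpm, 2L, stats::quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(n), function(k) {
    if (k == ref) return(1)
    .tmm_pair(counts[, k], counts[, ref], N[k], N[ref], cfg)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample_id = colnames(counts),
                    library_size = as.numeric(N),
                    tmm_factor = f,
                    effective_library_size = as.numeric(N) * f,
                    stringsAsFactors = FALSE)
  attr(out, "reference_sample") <- colnames(counts)[ref]
  class(out) <- c("norm_factors", "data.frame")
  out
}

# One sample vs reference; doubly trimmed, weighted mean of M on log2 scale.
.tmm_pair <- function(yk, yr, Nk, Nr, cfg) {
  pos <- yk > 0 & yr > 0
  if (!any(pos))
    stop("no gene has positive counts in both sample and reference; TMM undefined")
  yk <- as.numeric(yk[pos]); yr <- as.numeric(yr[pos])
  pk <- yk / Nk; pr <- yr / Nr
  M <- log2(pk / pr)
  A <- 0.5 * log2(pk * pr)
  ng <- length(M)
  loM <- floor(ng * cfg$logratio_trim) + 1L
  hiM <- ng + 1L - loM
  loA <- floor(ng * cfg$abs_intensity_trim) + 1L
  hiA <- ng + 1L - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warning("no genes survived TMM trimming; falling back to untrimmed mean")
    keep <- rep(TRUE, ng)
  }
  w <- if (cfg$weighting)
    1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  else rep(1, ng)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Reads per kilobase per million mapped reads
#'
#' `value(g, k) = counts(g, k) * 1e9 / (length_bp(g) * effective_library_size(k))`,
#' where the effective library size is the raw library size scaled by the TMM
#' factor (normalization happens before the RPKM conversion).
#'
#' @param m a [count_matrix()].
#' @param ann a [gene_annotation()] covering every gene of `m`.
#' @param nf [tmm_factors()] output covering every sample of `m`.
#' @return An [expr_matrix()] with unit `"RPKM"`.
#' @export
compute_rpkm <- function(m, ann, nf) {
  stopifnot(inherits(m, "count_matrix"), inherits(nf, "norm_factors"))
  genes <- rownames(m$counts)
  idx <- match(genes, ann$symbol)
  if (anyNA(idx))
    stop("gene length missing for: ",
         paste(utils::head(genes[is.na(idx)], 10L), collapse = ", "))
  len <- ann$length_bp[idx]
  sidx <- match(colnames(m$counts), nf$sample_id)
  if (anyNA(sidx))
    stop("normalization factors missing for sample(s): ",
         paste(colnames(m$counts)[is.na(sidx)], collapse = ", "))
  eff <- nf$effective_library_size[sidx]
  v <- m$counts * 1e9 / outer(len, eff)
  dimnames(v) <- dimnames(m$counts)
  expr_matrix(v, unit = "RPKM",
              provenance = paste0("rpkm(", m$cohort_id, ", tmm-effective libs)"))
}

#' Expression-distribution summary
#'
#' Log-scale quantiles (5/25/50/75/95%) of all matrix values and of a gene
#' subset (e.g. GPCRs only), on the `log2(x + 1)` scale. This is the numeric
#' backbone of the usual all-genes-versus-GPCRs density comparison; plotting
#' is left to the caller.
#'
#' @param e an [expr_matrix()].
#' @param gene_subset character vector of gene symbols, or `NULL` for none.
#' @return A list with `n_genes`, `n_subset`, `quantiles_all`,
#'   `quantiles_subset` (named numeric vectors, `log2(x+1)` scale).
#' @export
distribution_summary <- function(e, gene_subset = NULL) {
  stopifnot(inherits(e, "expr_matrix"))
  probs <- c(0.05, 0.25, 0.50, 0.75, 0.95)
  qa <- stats::quantile(log2(e + 1), probs = probs, na.rm = TRUE)
  sub <- intersect(gene_subset, rownames(e))
  if (length(gene_subset) && !length(sub)) {
    warning("gene subset is empty after matching; returning empty subset summary")
  }
  qs <- if (length(sub))
    stats::quantile(log2(e[sub, , drop = FALSE] + 1), probs = probs, na.rm = TRUE)
  else stats::setNames(rep(NA_real_, length(probs)), names(qa))
  list(n_genes = nrow(e), n_subset = length(sub),
       quantiles_all = qa, quantiles_subset = qs)
}
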