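#' Selection cascade configuration
#'
#' Thresholds of the three-stage target-selection cascade. All comparisons use
#' `>=` ("at least" semantics), so boundary cases pass.
#'
#' @param level_threshold_pct expression call threshold, percent of the
#'   reference gene (default 40).
#' @param within_cohort_fraction fraction of a cohort's samples that must meet
#'   the level threshold for a gene to be called expressed there (default 0.30).
#' @param min_cohorts minimum number of cohorts a gene must be called
#'   expressed in to be preselected (default 3).
#' @param sd_multiplier healthy-baseline cutoff is
#'   `mean_healthy + sd_multiplier * sd_healthy` (default 2).
#' @param pooled_fraction fraction of pooled cancer samples that must exceed
#'   the healthy cutoff for a gene to be retained (default 0.65).
#' @param healthy_tissue_scope `"peritoneal_only"` (default) restricts the
#'   healthy baseline to peritoneal samples; `"all_healthy"` uses every
#'   healthy sample.
#' @param healthy_filter_scale scale on which the healthy filter is applied:
#'   `"RPKM"` (default) or `"PCT_REF"` (percent of reference gene).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(level_threshold_pct = 40,
                             within_cohort_fraction = 0.30,
                             min_cohorts = 3L,
                             sd_multiplier = 2,
                             pooled_fraction = 0.65,
                             healthy_tissue_scope = c("peritoneal_only", "all_healthy"),
                             healthy_filter_scale = c("RPKM", "PCT_REF")) {
  stopifnot(level_threshold_pct >= 0, sd_multiplier >= 0,
            within_cohort_fraction > 0, within_cohort_fraction <= 1,
            pooled_fraction > 0, pooled_fraction <= 1,
            min_cohorts >= 1)
  structure(list(level_threshold_pct = level_threshold_pct,
                 within_cohort_fraction = within_cohort_fraction,
                 min_cohorts = as.integer(min_cohorts),
                 sd_multiplier = sd_multiplier,
                 pooled_fraction = pooled_fraction,
                 healthy_tissue_scope = match.arg(healthy_tissue_scope),
                 healthy_filter_scale = match.arg(healthy_filter_scale)),
            class = "selection_config")
}

#' Call expressed GPCRs in one cohort
#'
#' A GPCR is called expressed when its expression reaches at least
#' `level_threshold_pct` percent of the reference gene in at least
#' `within_cohort_fraction` of the cohort's samples. Unavailable cells (`NA`)
#' are excluded from both numerator and denominator of the sample fraction.
#'
#' @param pct an [expr_matrix()] with unit `"PCT_REF"`.
#' @param gpcrs character vector of GPCR-flagged symbols.
#' @param cfg a [selection_config()].
#' @return Sorted character vector of called symbols.
#' @export
call_expressed <- function(pct, gpcrs, cfg = selection_config()) {
  .assert_unit(pct, "PCT_REF")
  genes <- intersect(rownames(pct), gpcrs)
  if (!length(genes)) stop("no GPCR-flagged gene present in the matrix")
  called <- vapply(genes, function(g) {
    x <- pct[g, ]
    avail <- !is.na(x)
    if (!any(avail)) return(FALSE)
    sum(x[avail] >= cfg$level_threshold_pct) / sum(avail) >=
      cfg$within_cohort_fraction
  }, logical(1))
  sort(genes[called])
}

#' Cross-cohort expression frequency
#'
#' Counts, for each gene, the number of cohorts whose expressed set contains
#' it, and preselects genes present in at least `min_cohorts` cohorts.
#'
#' @param sets named list: cohort id -> character vector of expressed genes.
#' @param cfg a [selection_config()].
#' @return A list with `frequency` (named integer vector, sorted by
#'   decreasing frequency then alphabetically), `preselected` (sorted
#'   symbols), `n_cohorts`, and `all_cohort_genes` (genes expressed in every
#'   cohort).
#' @export
cohort_frequency <- function(sets, cfg = selection_config()) {
  if (!length(sets)) stop("at least one cohort set is required")
  sets <- lapply(sets, unique)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  freq <- vapply(genes, function(g)
    sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
  freq <- freq[order(-freq, names(freq))]
  list(frequency = freq,
       preselected = sort(names(freq)[freq >= cfg$min_cohorts]),
       n_cohorts = length(sets),
       all_cohort_genes = sort(names(freq)[freq == length(sets)]))
}

#' Healthy-tissue baseline statistics
#'
#' Per-gene mean and sample standard deviation (n - 1) over the in-scope
#' healthy samples, on the configured scale. With scope `"peritoneal_only"`
#' only healthy samples with tissue label `"peritoneal"` enter the baseline.
#'
#' @param e_healthy an [expr_matrix()] of the healthy cohort on the scale
#'   configured in `cfg$healthy_filter_scale`.
#' @param meta data.frame with columns `sample_id`, `condition`, `tissue`.
#' @param genes symbols to compute the baseline for; genes absent from
#'   `e_healthy` are treated as not expressed (mean 0, sd 0).
#' @param cfg a [selection_config()].
#' @return A data.frame of class `healthy_stats` with columns `gene`,
#'   `mean_healthy`, `sd_healthy`; attributes `n_healthy` and `scale`.
#' @export
healthy_reference_stats <- function(e_healthy, meta, genes,
                                    cfg = selection_config()) {
  stopifnot(inherits(e_healthy, "expr_matrix"))
  h <- meta[meta$condition == "healthy", , drop = FALSE]
  if (cfg$healthy_tissue_scope == "peritoneal_only") {
    if (anyNA(h$tissue))
      stop("healthy samples must carry a tissue label for peritoneal_only scope")
    h <- h[h$tissue == "peritoneal", , drop = FALSE]
  }
  ids <- intersect(h$sample_id, colnames(e_healthy))
  if (length(ids) < 2L)
    stop("need >= 2 in-scope healthy samples, got ", length(ids))
  sub <- unclass(e_healthy)[, ids, drop = FALSE]
  st <- t(vapply(genes, function(g) {
    if (!g %in% rownames(sub)) return(c(0, 0))
    x <- sub[g, ]
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(c(0, 0))
    c(mean(x), stats::sd(x))
  }, numeric(2)))
  out <- data.frame(gene = genes, mean_healthy = st[, 1L],
                    sd_healthy = st[, 2L], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_healthy") <- length(ids)
  attr(out, "scale") <- cfg$healthy_filter_scale
  class(out) <- c("healthy_stats", "data.frame")
  out
}

#' Healthy-baseline overexpression filter
#'
#' Retains candidate genes whose expression in the pooled cancer samples lies
#' at least `sd_multiplier` standard deviations above the healthy mean
#' (`cutoff = mean_healthy + sd_multiplier * sd_healthy`) in at least
#' `pooled_fraction` of samples. Unavailable cells are excluded from both
#' numerator and denominator.
#'
#' @param pooled_cancer an [expr_matrix()] concatenating all cancer cohorts on
#'   the configured scale (genes x pooled samples; `NA` = unavailable).
#' @param stats a [healthy_reference_stats()] result.
#' @param candidates symbols to test; must all appear in `stats` and in
#'   `pooled_cancer`.
#' @param cfg a [selection_config()].
#' @return A list with `final_targets` (sorted symbols), `pass_fraction`
#'   (named numeric over candidates) and `cutoff` (named numeric).
#' @export
healthy_overexpression_filter <- function(pooled_cancer, stats, candidates,
                                          cfg = selection_config()) {
  stopifnot(inherits(pooled_cancer, "expr_matrix"), inherits(stats, "healthy_stats"))
  if (!length(candidates)) stop("empty candidate list")
  miss <- setdiff(candidates, stats$gene)
  if (length(miss)) stop("candidates missing from healthy stats: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(candidates, rownames(pooled_cancer))
  if (length(miss)) stop("candidates missing from pooled matrix: ",
                         paste(miss, collapse = ", "))
  idx <- match(candidates, stats$gene)
  cutoff <- stats$mean_healthy[idx] + cfg$sd_multiplier * stats$sd_healthy[idx]
  names(cutoff) <- candidates
  pass <- vapply(candidates, function(g) {
    x <- pooled_cancer[g, ]
    avail <- !is.na(x)
    if (!any(avail)) return(0)
    sum(x[avail] >= cutoff[[g]]) / sum(avail)
  }, numeric(1))
  list(final_targets = sort(candidates[pass >= cfg$pooled_fraction]),
       pass_fraction = pass, cutoff = cutoff)
}

#' Marginal and pairwise expressed-sample fractions
#'
#' A sample expresses a gene when its percent-of-reference value reaches
#' `level_threshold_pct`. Marginal fractions exclude samples where the gene is
#' unavailable; the pairwise fraction excludes samples where either gene is
#' unavailable.
#'
#' @param pooled_pct an [expr_matrix()] with unit `"PCT_REF"` over pooled
#'   samples.
#' @param gene_a,gene_b gene symbols.
#' @param cfg a [selection_config()].
#' @return A list with `fraction_a`, `fraction_b`, `fraction_both`.
#' @export
coexpression_fraction <- function(pooled_pct, gene_a, gene_b,
                                  cfg = selection_config()) {
  .assert_unit(pooled_pct, "PCT_REF")
  for (g in c(gene_a, gene_b))
    if (!g %in% rownames(pooled_pct)) stop("gene '", g, "' absent from matrix")
  xa <- pooled_pct[gene_a, ]
  xb <- pooled_pct[gene_b, ]
  ea <- xa >= cfg$level_threshold_pct
  eb <- xb >= cfg$level_threshold_pct
  frac <- function(ind) {
    ok <- !is.na(ind)
    if (!any(ok)) return(NA_real_)
    sum(ind[ok]) / sum(ok)
  }
  both <- ea & eb
  both[is.na(ea) | is.na(eb)] <- NA  # either gene unavailable -> sample excluded
  list(fraction_a = frac(ea), fraction_b = frac(eb),
       fraction_both = frac(both))
}

#' Assemble a selection report
#'
#' Bundles the cascade outputs and asserts the containment invariant
#' `final_targets` within `preselected` within the per-cohort union.
#'
#' @param per_cohort_expressed named list: cohort -> expressed GPCR symbols.
#' @param frequency named integer vector from [cohort_frequency()].
#' @param preselected preselected symbols.
#' @param final_targets symbols surviving the healthy filter.
#' @param pass_fraction named numeric from [healthy_overexpression_filter()].
#' @param coexpression optional named numeric of pairwise expressed fractions
#'   (`"A|B"` names).
#' @return A list of class `selection_report`.
#' @export
selection_report <- function(per_cohort_expressed, frequency, preselected,
                             final_targets, pass_fraction,
                             coexpression = NULL) {
  union_all <- sort(unique(unlist(per_cohort_expressed, use.names = FALSE)))
  if (!all(preselected %in% union_all))
    stop("invariant violated: preselected genes outside per-cohort union")
  if (!all(final_targets %in% preselected))
    stop("invariant violated: final targets outside preselected set")
  structure(list(per_cohort_expressed = per_cohort_expressed,
                 frequency = frequency, preselected = preselected,
                 final_targets = final_targets, pass_fraction = pass_fraction,
                 coexpression = coexpression),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  cohorts: ", length(x$per_cohort_expressed),
      " (expressed GPCRs per cohort: ",
      paste(vapply(x$per_cohort_expressed, length, integer(1)), collapse = "/"),
      ")\n", sep = "")
  cat("  preselected (cross-cohort): ", length(x$preselected), "\n", sep = "")
  cat("  final targets (healthy filter): ", length(x$final_targets), "\n", sep = "")
  if (length(x$final_targets))
    cat("  ", paste(x$final_targets, collapse = ", "), "\n", sep = "")
  invisible(x)
}
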