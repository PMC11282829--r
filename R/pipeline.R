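#' Run the full GPCR target-screening cascade
#'
#' Executes, per cancer cohort: low-expression filtering, TMM scaling, RPKM
#' conversion and percent-of-reference transformation; selects the
#' housekeeping reference gene by CV% on the healthy cohort; calls expressed
#' GPCRs per cohort; ranks them by cross-cohort frequency; retains genes
#' overexpressed versus the healthy baseline (mean + `sd_multiplier` SD in at
#' least `pooled_fraction` of the pooled cancer samples); and clusters the
#' pooled cancer samples on the final panel. Genes filtered out of a cohort
#' are treated as not expressed there and as unavailable when pooling.
#'
#' @param cohorts named list of cancer-cohort [count_matrix()] objects.
#' @param healthy a [count_matrix()] of the healthy reference cohort, or
#'   `NULL` (the run then stops before the healthy filter with an error).
#' @param annotation a [gene_annotation()].
#' @param meta sample metadata data.frame (columns `sample_id`, `cohort_id`,
#'   `condition`, `tissue`, ...).
#' @param filter a [filter_config()].
#' @param tmm a [tmm_config()].
#' @param selection a [selection_config()].
#' @param clustering a [cluster_config()]; `k` is capped at the number of
#'   pooled samples.
#' @param candidates housekeeping candidate symbols (default
#'   [hk_candidates()]).
#' @param verbose log the selection funnel per stage (default `TRUE`).
#' @return An object of class `gpcr_screen`: a list with `report`
#'   (`selection_report`), `refgene` (`refgene_report`), `healthy_stats`,
#'   `clusters` (`cluster_assignment`, or `NULL` if the panel is empty),
#'   `pooled_pct` (pooled percent-of-reference matrix on the preselected
#'   genes), `funnel` (gene counts after each stage) and `config`.
#' @examples
#' sim <- simulate_collection(synthetic_spec(seed = 42))
#' scr <- gpcr_screen(sim$cohorts[names(sim$cohorts) != "healthy"],
#'                    sim$cohorts$healthy, sim$annotation, sim$meta,
#'                    verbose = FALSE)
#' print(scr)
#' identical(scr$report$final_targets, sim$truth$planted)
#' @export
gpcr_screen <- function(cohorts, healthy, annotation, meta,
                        filter = filter_config(), tmm = tmm_config(),
                        selection = selection_config(),
                        clustering = cluster_config(),
                        candidates = hk_candidates(), verbose = TRUE) {
  say <- if (verbose) function(...) message(...) else function(...) invisible()
  if (!length(cohorts) || !all(vapply(cohorts, inherits, logical(1), "count_matrix")))
    stop("stage input: 'cohorts' must be a non-empty list of count_matrix objects")
  if (anyDuplicated(unlist(lapply(c(cohorts, list(healthy)), function(m)
    if (is.null(m)) NULL else colnames(m$counts)))))
    stop("stage input: sample ids must be unique across the whole analysis")
  if (is.null(healthy))
    stop("stage healthy_filter: no healthy cohort supplied; ",
         "a healthy baseline is required before the overexpression filter")
  gpcrs <- annotation$symbol[annotation$is_gpcr]

  # per-cohort normalization: filter -> TMM -> RPKM
  norm_one <- function(m) {
    f <- filter_low_expression(m, filter)
    say("  [", m$cohort_id, "] low-expression filter: ", nrow(m$counts),
        " -> ", nrow(f$counts), " genes")
    nf <- tmm_factors(f, tmm)
    compute_rpkm(f, annotation, nf)
  }
  say("stage normalize:")
  rpkm <- lapply(cohorts, norm_one)
  rpkm_healthy <- norm_one(healthy)

  # reference gene on the healthy cohort
  ref <- select_reference(rpkm_healthy, candidates, cohort_id = healthy$cohort_id)
  say("stage reference_gene: selected ", ref$selected, " (CV ",
      sprintf("%.1f%%", ref$candidate_cv[[ref$selected]]), ")")

  # percent-of-reference and per-cohort expressed calls
  pct <- lapply(rpkm, relative_to_reference, ref = ref$selected)
  pct_healthy <- relative_to_reference(rpkm_healthy, ref$selected)
  sets <- lapply(pct, call_expressed, gpcrs = gpcrs, cfg = selection)
  say("stage call_expressed: ",
      paste(names(sets), vapply(sets, length, integer(1)), sep = "=",
            collapse = ", "), " GPCRs")

  freq <- cohort_frequency(sets, selection)
  say("stage cohort_frequency: ", length(freq$preselected),
      " genes in >= ", selection$min_cohorts, " cohorts (",
      length(freq$all_cohort_genes), " in all ", freq$n_cohorts, ")")

  if (!length(freq$preselected)) {
    say("stage healthy_filter: no preselected genes; empty panel")
    report <- selection_report(sets, freq$frequency, character(0), character(0),
                               stats::setNames(numeric(0), character(0)))
    return(.gpcr_screen_obj(report, ref, NULL, NULL, NULL, filter, tmm,
                            selection, clustering))
  }

  # healthy baseline + pooled cancer matrix on the configured scale
  scale_mats <- if (selection$healthy_filter_scale == "RPKM") rpkm else pct
  scale_healthy <- if (selection$healthy_filter_scale == "RPKM")
    rpkm_healthy else pct_healthy
  hstats <- healthy_reference_stats(scale_healthy, meta, freq$preselected,
                                    selection)
  pooled <- pool_expression(scale_mats, freq$preselected)
  filt <- healthy_overexpression_filter(pooled, hstats, freq$preselected,
                                        selection)
  say("stage healthy_filter: ", length(freq$preselected), " -> ",
      length(filt$final_targets), " final targets (baseline n = ",
      attr(hstats, "n_healthy"), " healthy samples)")

  # co-expression summaries on the pooled percent-of-reference scale
  pooled_pct <- pool_expression(pct, freq$preselected)
  coex <- NULL
  fin <- filt$final_targets
  if (length(fin) >= 2L) {
    prs <- utils::combn(fin, 2L)
    coex <- apply(prs, 2L, function(p)
      coexpression_fraction(pooled_pct, p[1L], p[2L], selection)$fraction_both)
    names(coex) <- paste(prs[1L, ], prs[2L, ], sep = "|")
  }

  report <- selection_report(sets, freq$frequency, freq$preselected,
                             fin, filt$pass_fraction, coex)

  clusters <- NULL
  if (length(fin)) {
    panel_pct <- expr_matrix(unclass(pooled_pct)[fin, , drop = FALSE],
                             unit = "PCT_REF",
                             provenance = "pooled cancer samples, final panel")
    ccfg <- clustering
    ccfg$k <- min(ccfg$k, ncol(panel_pct))
    clusters <- hierarchical_clusters(sample_distance(panel_pct, ccfg), ccfg)
    say("stage clustering: ", ccfg$k, " clusters (sizes ",
        paste(clusters$sizes, collapse = ", "), ")")
  }

  .gpcr_screen_obj(report, ref, hstats, clusters, pooled_pct,
                   filter, tmm, selection, clustering)
}

.gpcr_screen_obj <- function(report, ref, hstats, clusters, pooled_pct,
                             filter, tmm, selection, clustering) {
  structure(list(report = report, refgene = ref, healthy_stats = hstats,
                 clusters = clusters, pooled_pct = pooled_pct,
                 funnel = c(per_cohort = length(report$per_cohort_expressed),
                            expressed_union =
                              length(unique(unlist(report$per_cohort_expressed))),
                            preselected = length(report$preselected),
                            final = length(report$final_targets)),
                 config = list(filter = filter, tmm = tmm,
                               selection = selection, clustering = clustering)),
            class = "gpcr_screen")
}

#' Pool expression matrices across cohorts
#'
#' Column-binds cohort matrices over a common gene set; a gene missing from a
#' cohort (e.g. removed by its low-expression filter) is `NA` (unavailable)
#' in that cohort's columns. No re-normalization is performed beyond each
#' cohort's own scaling.
#'
#' @param mats list of [expr_matrix()] objects sharing a unit.
#' @param genes gene symbols forming the pooled rows.
#' @return An [expr_matrix()] of the shared unit, `genes` x all samples.
#' @export
pool_expression <- function(mats, genes) {
  units <- unique(vapply(mats, function(m) attr(m, "unit"), character(1)))
  if (length(units) != 1L) stop("cannot pool matrices with mixed units")
  cols <- lapply(mats, function(m) {
    out <- matrix(NA_real_, length(genes), ncol(m),
                  dimnames = list(genes, colnames(m)))
    hit <- intersect(genes, rownames(m))
    out[hit, ] <- unclass(m)[hit, , drop = FALSE]
    out
  })
  expr_matrix(do.call(cbind, cols), unit = units,
              provenance = "pooled across cohorts (no re-normalization)")
}

#' @export
print.gpcr_screen <- function(x, ...) {
  cat("GPCR target screen\n")
  cat("  reference gene: ", x$refgene$selected, " (CV ",
      sprintf("%.1f%%", x$refgene$candidate_cv[[x$refgene$selected]]),
      ")\n", sep = "")
  cat("  cohorts screened: ", x$funnel[["per_cohort"]], "\n", sep = "")
  cat("  expressed GPCRs (union): ", x$funnel[["expressed_union"]],
      "  ->  preselected: ", x$funnel[["preselected"]],
      "  ->  final targets: ", x$funnel[["final"]], "\n", sep = "")
  if (length(x$report$final_targets))
    cat("  panel: ", paste(x$report$final_targets, collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$clusters))
    cat("  clustering: ", x$clusters$k, " clusters (sizes ",
        paste(x$clusters$sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.gpcr_screen <- function(object, ...) {
  print(object)
  rep <- object$report
  if (length(rep$final_targets)) {
    cat("\n  pass fraction vs healthy cutoff (final panel):\n")
    pf <- sort(rep$pass_fraction[rep$final_targets], decreasing = TRUE)
    for (g in names(pf))
      cat(sprintf("    %-10s %5.1f%%\n", g, 100 * pf[[g]]))
  }
  if (!is.null(rep$coexpression) && length(rep$coexpression)) {
    top <- sort(rep$coexpression, decreasing = TRUE)[1L]
    cat(sprintf("\n  most co-expressed pair: %s (%.0f%% of samples)\n",
                names(top), 100 * top))
  }
  invisible(object)
}

#' Plot the sample dendrogram of a screen
#'
#' @param x a `gpcr_screen` with a non-empty final panel.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.gpcr_screen <- function(x, ...) {
  if (is.null(x$clusters)) stop("no clustering available (empty final panel)")
  graphics::plot(x$clusters$hclust, labels = FALSE, hang = -1,
                 main = "Pooled cancer samples on the final GPCR panel",
                 xlab = "", sub = "", ...)
  stats::rect.hclust(x$clusters$hclust, k = x$clusters$k)
  invisible(x)
}
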