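#' Clustering configuration
#'
#' @param k number of clusters to cut the dendrogram into (default 12).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation).
#' @param linkage `"ward"` (default; Ward's minimum-variance on squared
#'   Euclidean distances), `"average"` or `"complete"`.
#' @param missing_policy how unavailable cells are handled when computing
#'   distances: `"zero_impute"` (default; unavailable = not expressed) or
#'   `"pairwise_scale"` (drop the coordinate for that pair and rescale).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(k = 12L,
                           distance = c("euclidean", "correlation"),
                           linkage = c("ward", "average", "complete"),
                           missing_policy = c("zero_impute", "pairwise_scale")) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), distance = match.arg(distance),
                 linkage = match.arg(linkage),
                 missing_policy = match.arg(missing_policy)),
            class = "cluster_config")
}

#' Between-sample distance matrix
#'
#' Samples are the columns of the expression matrix; genes are the
#' coordinates. Under `zero_impute`, unavailable cells are set to 0 before
#' computing distances; under `pairwise_scale`, Euclidean distances use only
#' coordinates available in both samples, rescaled by the fraction of usable
#' coordinates (the base `stats::dist` convention).
#'
#' @param pct an [expr_matrix()] (typically percent-of-reference values on the
#'   final target panel).
#' @param cfg a [cluster_config()].
#' @return A symmetric `dist` object over samples.
#' @export
sample_distance <- function(pct, cfg = cluster_config()) {
  stopifnot(inherits(pct, "expr_matrix"))
  x <- t(unclass(pct))  # samples in rows
  if (nrow(x) < 2L) stop("need >= 2 samples to compute distances")
  allna <- rowSums(!is.na(x)) == 0L
  if (any(allna))
    stop("sample(s) with all values unavailable: ",
         paste(rownames(x)[allna], collapse = ", "))
  if (cfg$missing_policy == "zero_impute") x[is.na(x)] <- 0
  if (cfg$distance == "euclidean") {
    stats::dist(x, method = "euclidean")
  } else {
    co <- stats::cor(t(x), use = "pairwise.complete.obs")
    stats::as.dist(1 - co)
  }
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering with the configured linkage, cut into `k`
#' clusters. Cluster labels are renumbered by first appearance in sample
#' order, so label 1 always contains the first sample. The merge history is
#' kept so the dendrogram can be re-cut at any k.
#'
#' @param d a `dist` object from [sample_distance()].
#' @param cfg a [cluster_config()].
#' @return A list of class `cluster_assignment` with `labels` (named integer
#'   vector, sample -> 1..k), `k`, `sizes`, and `hclust` (the merge tree).
#' @export
hierarchical_clusters <- function(d, cfg = cluster_config()) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  if (cfg$k > n) stop("k = ", cfg$k, " exceeds the number of samples (", n, ")")
  method <- switch(cfg$linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  hc <- stats::hclust(d, method = method)
  raw <- stats::cutree(hc, k = cfg$k)
  labels <- match(raw, unique(raw))  # renumber by first appearance
  names(labels) <- names(raw)
  structure(list(labels = labels, k = cfg$k,
                 sizes = as.integer(table(labels)), hclust = hc),
            class = "cluster_assignment")
}

#' Re-cut a stored dendrogram at a different k
#'
#' @param x a `cluster_assignment`.
#' @param k new number of clusters.
#' @return Named integer vector of labels (first-appearance numbering).
#' @export
recut_clusters <- function(x, k) {
  stopifnot(inherits(x, "cluster_assignment"))
  raw <- stats::cutree(x$hclust, k = k)
  labels <- match(raw, unique(raw))
  names(labels) <- names(raw)
  labels
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> ", length(x$labels), " samples in ", x$k,
      " clusters (sizes ", paste(x$sizes, collapse = ", "), ")\n", sep = "")
  invisible(x)
}
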