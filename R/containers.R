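#' Count matrix for one cohort
#'
#' Lightweight container tying a genes x samples matrix of raw sequencing
#' counts to a cohort identifier. Library sizes are always the exact column
#' sums of the stored counts.
#'
#' @param counts integer-valued matrix, genes in rows (rownames = HGNC-style
#'   symbols), samples in columns (colnames = sample ids).
#' @param cohort_id single string naming the cohort (e.g. a GEO accession).
#' @return An object of class `count_matrix`: a list with elements
#'   `cohort_id`, `counts` (integer matrix) and `library_sizes` (named numeric
#'   vector of column sums).
#' @export
count_matrix <- function(counts, cohort_id) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L, nzchar(cohort_id))
  counts <- as.matrix(counts)
  if (length(counts) == 0L) stop("empty count matrix for cohort '", cohort_id, "'")
  if (is.null(rownames(counts)) || any(!nzchar(rownames(counts))))
    stop("count matrix must carry non-empty gene symbols as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stop("count matrix must carry unique sample ids as colnames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: gene '%s', sample '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, 1], bad[1, 2]])))
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    message("collapsing ", length(dup), " duplicated gene symbol(s) by summation: ",
            paste(utils::head(dup, 5L), collapse = ", "),
            if (length(dup) > 5L) ", ..." else "")
    counts <- rowsum(counts, group = rownames(counts), reorder = FALSE)
  }
  storage.mode(counts) <- "integer"
  structure(
    list(cohort_id = cohort_id, counts = counts,
         library_sizes = colSums(counts)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> cohort '", x$cohort_id, "': ",
      nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  cat("  library sizes: ",
      paste(format(utils::head(x$library_sizes, 4L), big.mark = ","), collapse = ", "),
      if (ncol(x$counts) > 4L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Normalized expression matrix
#'
#' A genes x samples matrix of non-negative real expression values carrying an
#' explicit unit tag. `NA` cells mean "value not available" (e.g. the reference
#' gene was zero in that sample when expressing values as a percentage of the
#' reference).
#'
#' @param values numeric matrix with gene rownames and sample colnames.
#' @param unit one of `"CPM"`, `"RPKM"`, `"PCT_REF"`.
#' @param provenance character scalar describing the upstream transforms.
#' @return A matrix of class `expr_matrix` with attributes `unit` and
#'   `provenance`.
#' @export
expr_matrix <- function(values, unit = c("CPM", "RPKM", "PCT_REF"),
                        provenance = "") {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(!is.na(values) & (!is.finite(values) | values < 0)))
    stop("expression values must be finite and non-negative (NA = unavailable)")
  structure(values, unit = unit, provenance = provenance,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> [", attr(x, "unit"), "] ",
      nrow(x), " genes x ", ncol(x), " samples; ",
      sum(is.na(x)), " unavailable cell(s)\n", sep = "")
  if (nzchar(attr(x, "provenance")))
    cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param e an [expr_matrix()].
#' @return The unit string.
#' @export
expr_unit <- function(e) attr(e, "unit")

.assert_unit <- function(e, unit) {
  if (!inherits(e, "expr_matrix") || !identical(attr(e, "unit"), unit))
    stop("expected an expr_matrix with unit ", unit)
  invisible(e)
}
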