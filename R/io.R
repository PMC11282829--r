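#' Read a raw count matrix
#'
#' Accepts either a delimited text file (gene-symbol first column, one column
#' per sample; tab or comma separation is sniffed from the header line) or a
#' MatrixMarket triplet directory containing `matrix.mtx`, `genes.tsv` and
#' `samples.tsv`. Duplicate gene symbols are collapsed by summation and
#' reported.
#'
#' @param path file path (TSV/CSV) or directory path (MTX triplet).
#' @param cohort_id cohort identifier attached to the matrix.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, cohort_id) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx))
      stop("directory '", path, "' does not contain matrix.mtx")
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- readLines(file.path(path, "genes.tsv"))
    samples <- readLines(file.path(path, "samples.tsv"))
    if (nrow(m) != length(genes) || ncol(m) != length(samples))
      stop("MTX dimensions do not match genes.tsv/samples.tsv")
    dimnames(m) <- list(genes, samples)
    return(count_matrix(m, cohort_id))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("count file needs a gene column plus >=1 sample column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  count_matrix(m, cohort_id)
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a gene annotation table
#'
#' @param path TSV/CSV with columns `symbol`, `length_bp`, `is_gpcr`.
#' @return A data.frame of class `gene_annotation` with character `symbol`,
#'   integer `length_bp` and logical `is_gpcr`; the number of GPCR-flagged
#'   genes is reported.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  gene_annotation(df)
}

#' Construct/validate a gene annotation table
#'
#' @param df data.frame with columns `symbol` (unique, non-empty), `length_bp`
#'   (positive integers, transcript length in base pairs) and `is_gpcr`
#'   (logical or 0/1).
#' @return The validated annotation data.frame (class `gene_annotation`).
#' @export
gene_annotation <- function(df) {
  need <- c("symbol", "length_bp", "is_gpcr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$symbol <- as.character(df$symbol)
  if (any(!nzchar(df$symbol)) || anyDuplicated(df$symbol))
    stop("annotation symbols must be unique and non-empty")
  if (any(!is.finite(df$length_bp) | df$length_bp < 1 |
          df$length_bp != round(df$length_bp)))
    stop("length_bp must be positive integers (>= 1 bp)")
  df$length_bp <- as.integer(df$length_bp)
  df$is_gpcr <- as.logical(df$is_gpcr)
  if (anyNA(df$is_gpcr)) stop("is_gpcr must be logical (TRUE/FALSE or 0/1)")
  message("annotation: ", nrow(df), " genes, ", sum(df$is_gpcr), " GPCR-flagged")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a qPCR cycle-threshold table
#'
#' Long format: one row per well with columns `sample_id`, `gene`, `ct`.
#' Replicate wells (same sample and gene) are averaged; the across-replicate
#' standard deviation is retained.
#'
#' @param path TSV/CSV file.
#' @param reference_gene symbol of the internal-standard housekeeping gene.
#' @param detection_limit cycles; Ct above this is treated as below the limit
#'   of mRNA detection.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, reference_gene = "SDHA", detection_limit = 35) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- .sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct file is missing column(s): ", paste(miss, collapse = ", "))
  genes <- unique(df$gene)
  samples <- unique(df$sample_id)
  ct <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  ct_sd <- ct
  agg_m <- tapply(df$ct, list(df$gene, df$sample_id), mean, na.rm = TRUE)
  agg_s <- tapply(df$ct, list(df$gene, df$sample_id), stats::sd, na.rm = TRUE)
  ct[rownames(agg_m), colnames(agg_m)] <- agg_m
  ct_sd[rownames(agg_s), colnames(agg_s)] <- agg_s
  ct_table(ct, reference_gene = reference_gene,
           detection_limit = detection_limit, replicate_sd = ct_sd)
}

#' Construct/validate a Ct table
#'
#' @param ct numeric matrix of cycle-threshold values, genes x samples;
#'   `NA` = no amplification recorded.
#' @param reference_gene internal-standard gene; must be a row of `ct`.
#' @param detection_limit cycles (default 35).
#' @param replicate_sd optional matrix of across-replicate SDs, same shape.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, reference_gene = "SDHA", detection_limit = 35,
                     replicate_sd = NULL) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs gene rownames and sample colnames")
  if (any(!is.na(ct) & (ct <= 0 | ct >= 60)))
    stop("Ct values must lie in (0, 60) cycles")
  if (!reference_gene %in% rownames(ct))
    stop("reference gene '", reference_gene, "' not found in Ct table")
  structure(list(ct = ct, reference_gene = reference_gene,
                 detection_limit = detection_limit,
                 replicate_sd = replicate_sd),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat("<ct_table> ", nrow(x$ct), " genes x ", ncol(x$ct), " samples; reference ",
      x$reference_gene, "; detection limit ", x$detection_limit, " cycles\n",
      sep = "")
  invisible(x)
}

#' Write a selection report to disk
#'
#' Writes `report.json` (full machine-readable report) plus flat TSV tables:
#' `frequency.tsv` (gene, n_cohorts), `final_targets.tsv` (gene,
#' pass_fraction) and, when cluster labels are supplied, `clusters.tsv`
#' (sample_id, cluster). [read_report()] reconstructs the report exactly.
#'
#' @param report a `selection_report` (see [cohort_frequency()],
#'   [healthy_overexpression_filter()], [gpcr_screen()]).
#' @param dir output directory, created if needed.
#' @param clusters optional named vector of cluster labels (sample -> label).
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir, clusters = NULL) {
  if (!inherits(report, "selection_report")) stop("not a selection_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  ser <- unclass(report)
  # named atomic vectors lose their names in JSON arrays; store as objects
  ser$frequency <- as.list(ser$frequency)
  ser$pass_fraction <- as.list(ser$pass_fraction)
  if (!is.null(ser$coexpression)) ser$coexpression <- as.list(ser$coexpression)
  jsonlite::write_json(ser, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  freq <- data.frame(gene = names(report$frequency),
                     n_cohorts = as.integer(report$frequency))
  utils::write.table(freq, file.path(dir, "frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fin <- data.frame(gene = report$final_targets,
                    pass_fraction = as.numeric(report$pass_fraction[report$final_targets]))
  utils::write.table(fin, file.path(dir, "final_targets.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(clusters)) {
    cl <- data.frame(sample_id = names(clusters), cluster = as.integer(clusters))
    utils::write.table(cl, file.path(dir, "clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a selection report written by [write_report()]
#'
#' @param dir directory containing `report.json`.
#' @return The reconstructed `selection_report`.
#' @export
read_report <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path)) stop("no report.json under ", dir)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  relist <- function(v, mode) {
    out <- vapply(v, function(z) as.vector(z, mode), vector(mode, 1L))
    stats::setNames(out, names(v))
  }
  x$per_cohort_expressed <- lapply(x$per_cohort_expressed, as.character)
  x$frequency <- relist(x$frequency, "integer")
  x$preselected <- as.character(x$preselected)
  x$final_targets <- as.character(x$final_targets)
  x$pass_fraction <- relist(x$pass_fraction, "double")
  if (!is.null(x$coexpression))
    x$coexpression <- relist(x$coexpression, "double")
  structure(x, class = "selection_report")
}
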