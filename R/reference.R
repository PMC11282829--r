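#' Default housekeeping candidate genes
#'
#' Fifteen commonly used human housekeeping genes screened as internal
#' expression standards. The list is a package default and fully overridable;
#' it includes SDHA (succinate dehydrogenase complex flavoprotein subunit A),
#' GAPDH and ACTB.
#'
#' @return Character vector of 15 HGNC symbols.
#' @export
hk_candidates <- function() {
  c("ACTB", "B2M", "GAPDH", "GUSB", "HMBS", "HPRT1", "PGK1", "PPIA",
    "RPL13A", "RPLP0", "SDHA", "TBP", "TFRC", "UBC", "YWHAZ")
}

#' Coefficient of variation (percent)
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean, times
#' 100.
#'
#' @param values numeric vector of per-sample expression for one gene; at
#'   least two finite values with a positive mean.
#' @return CV as a percentage.
#' @export
cv_percent <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("CV% needs at least 2 finite values")
  m <- mean(values)
  if (m <= 0) stop("CV% undefined for non-positive mean")
  100 * stats::sd(values) / m
}

#' Select the housekeeping reference gene by CV%
#'
#' Computes CV% for every candidate present in the expression matrix (absent
#' candidates are reported and skipped) and selects the candidate with the
#' lowest CV%; ties are broken alphabetically.
#'
#' @param e an [expr_matrix()], typically RPKM of the designated (healthy)
#'   cohort.
#' @param candidates character vector of candidate symbols (default
#'   [hk_candidates()]).
#' @param cohort_id optional label recorded in the report.
#' @return A list of class `refgene_report` with `candidate_cv` (named, sorted
#'   ascending), `selected`, `cohort_id`, `absent`.
#' @export
select_reference <- function(e, candidates = hk_candidates(), cohort_id = NA_character_) {
  stopifnot(inherits(e, "expr_matrix"))
  present <- intersect(candidates, rownames(e))
  absent <- setdiff(candidates, present)
  if (!length(present)) stop("no candidate housekeeping gene present in the matrix")
  if (length(absent))
    message("candidate(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
  cv <- vapply(present, function(g) cv_percent(e[g, ]), numeric(1))
  cv <- cv[order(cv, names(cv))]  # ties resolved alphabetically
  ties <- names(cv)[cv == cv[1L]]
  if (length(ties) > 1L)
    message("CV% tie between ", paste(ties, collapse = ", "),
            "; selecting alphabetically first")
  structure(list(candidate_cv = cv, selected = names(cv)[1L],
                 cohort_id = cohort_id, absent = absent),
            class = "refgene_report")
}

#' @export
print.refgene_report <- function(x, ...) {
  cat("<refgene_report> selected ", x$selected, " (CV ",
      sprintf("%.1f%%", x$candidate_cv[[x$selected]]), ") among ",
      length(x$candidate_cv), " candidates\n", sep = "")
  invisible(x)
}

#' Express all genes relative to the reference gene
#'
#' `value(g, k) = 100 * e(g, k) / e(ref, k)`; the reference row becomes 100 in
#' every available sample. Samples in which the reference gene is zero (or
#' unavailable) cannot be expressed on this scale: their whole column is set
#' to `NA` ("value not available") and they are reported.
#'
#' @param e an [expr_matrix()] (any unit).
#' @param ref reference gene symbol; must be a row of `e`.
#' @return An [expr_matrix()] with unit `"PCT_REF"`; flagged samples in
#'   attribute `unavailable_samples`.
#' @export
relative_to_reference <- function(e, ref) {
  stopifnot(inherits(e, "expr_matrix"))
  if (!ref %in% rownames(e)) stop("reference gene '", ref, "' not in matrix")
  refrow <- e[ref, ]
  bad <- is.na(refrow) | refrow <= 0
  if (any(bad))
    message("reference gene zero/unavailable in ", sum(bad),
            " sample(s); marked unavailable: ",
            paste(utils::head(colnames(e)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
  denom <- ifelse(bad, NA_real_, refrow)
  v <- 100 * sweep(unclass(e), 2L, denom, "/")
  out <- expr_matrix(v, unit = "PCT_REF",
                     provenance = paste0("100 * x / ", ref, " | ",
                                         attr(e, "provenance")))
  attr(out, "unavailable_samples") <- colnames(e)[bad]
  out
}
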