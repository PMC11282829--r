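#' Delta-Ct relative quantification
#'
#' For every target gene and sample, `delta_ct = Ct(target) - Ct(reference)`.
#' Positive delta-Ct means less expressed than the reference. A measurement is
#' detected when its Ct is present and at or below the detection limit
#' (default 35 cycles; higher Ct is interpreted as mRNA below the limit of
#' detection). Samples whose reference-gene Ct is missing or above the limit
#' are flagged invalid and yield no delta-Ct. Fold reductions are
#' `(1 + E)^delta_ct` with amplification efficiency `E` (2^delta_ct at the
#' default E = 1).
#'
#' @param ct a [ct_table()].
#' @param efficiency amplification efficiency in (0, 1]; either a scalar or a
#'   named per-gene vector (genes not named fall back to 1).
#' @return A list of class `delta_ct_result` with matrices `delta_ct`,
#'   `detected`, `fold_reduction` (targets x samples; `NA` where not
#'   detected), plus `reference_gene`, `invalid_samples`, `efficiency`.
#' @export
delta_ct <- function(ct, efficiency = 1) {
  stopifnot(inherits(ct, "ct_table"))
  m <- ct$ct
  ref <- ct$reference_gene
  lim <- ct$detection_limit
  targets <- setdiff(rownames(m), ref)
  refct <- m[ref, ]
  invalid <- is.na(refct) | refct > lim
  tg <- m[targets, , drop = FALSE]
  detected <- !is.na(tg) & tg <= lim
  detected[, invalid] <- FALSE
  dct <- sweep(tg, 2L, refct, "-")
  dct[!detected] <- NA_real_
  eff <- .gene_efficiency(efficiency, targets)
  fold <- (1 + eff)^dct  # recycles eff down columns: one efficiency per gene
  fold[!detected] <- NA_real_
  structure(list(delta_ct = dct, detected = detected, fold_reduction = fold,
                 reference_gene = ref,
                 invalid_samples = colnames(m)[invalid],
                 efficiency = stats::setNames(eff, targets)),
            class = "delta_ct_result")
}

.gene_efficiency <- function(efficiency, targets) {
  if (any(efficiency <= 0 | efficiency > 1))
    stop("amplification efficiency must lie in (0, 1]")
  if (is.null(names(efficiency))) {
    if (length(efficiency) != 1L)
      stop("unnamed efficiency must be a scalar")
    rep(efficiency, length(targets))
  } else {
    e <- rep(1, length(targets))
    hit <- match(targets, names(efficiency))
    e[!is.na(hit)] <- efficiency[hit[!is.na(hit)]]
    e
  }
}

#' Delta-Ct to fold reduction
#'
#' How many times less expressed a target is than the reference:
#' `(1 + efficiency)^delta_ct`, i.e. `2^delta_ct` at 100% amplification
#' efficiency.
#'
#' @param delta_ct numeric delta-Ct value(s) in cycles.
#' @param efficiency amplification efficiency in (0, 1] (default 1).
#' @return Fold reduction(s), same shape as `delta_ct`.
#' @export
fold_reduction <- function(delta_ct, efficiency = 1) {
  if (any(efficiency <= 0 | efficiency > 1))
    stop("amplification efficiency must lie in (0, 1]")
  (1 + efficiency)^delta_ct
}

#' @export
print.delta_ct_result <- function(x, ...) {
  det <- x$detected
  cat("<delta_ct_result> ", nrow(x$delta_ct), " targets x ", ncol(x$delta_ct),
      " samples vs ", x$reference_gene, "\n", sep = "")
  cat("  detected: ", sum(det), "/", length(det), " cells",
      if (length(x$invalid_samples))
        paste0("; invalid sample(s): ", paste(x$invalid_samples, collapse = ", ")),
      "\n", sep = "")
  rng <- range(x$delta_ct, na.rm = TRUE)
  if (all(is.finite(rng)))
    cat(sprintf("  delta-Ct range %.2f-%.2f (%.2f- to %.0f-fold below reference)\n",
                rng[1], rng[2], fold_reduction(rng[1]), fold_reduction(rng[2])))
  invisible(x)
}
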