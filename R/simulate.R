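#' Specification of a synthetic multi-cohort collection
#'
#' Seeded generative configuration for a collection of bulk RNA-seq cohorts
#' with the statistical structure the screening cascade assumes: negative
#' binomial counts with variable library sizes, a panel of housekeeping genes
#' of which one (SDHA) is distinctly stable, GPCR-flagged genes biased towards
#' low-to-moderate expression, and a set of planted target GPCRs that are
#' overexpressed in the cancer cohorts but sit at a low baseline in healthy
#' tissue.
#'
#' Defaults mirror the study conditions of the screening design: five cancer
#' cohorts of 77, 9, 10, 20 and 35 samples (151 pooled) and one healthy
#' cohort of 9 samples split 3 peritoneal / 3 fallopian / 3 ovarian-surface.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output
#'   (Mersenne-Twister, R's default generator).
#' @param n_genes total gene count (default 2000).
#' @param gpcr_count number of GPCR-flagged genes (default 200); includes the
#'   planted targets.
#' @param cancer_cohort_sizes named integer vector of cancer cohort sizes.
#' @param healthy_tissues tissue labels of the healthy cohort, one per sample.
#' @param library_size_lognorm `c(meanlog, sdlog)` of per-sample library
#'   sizes.
#' @param dispersion negative-binomial dispersion of ordinary genes
#'   (default 0.2; variance = mu + dispersion * mu^2).
#' @param housekeeping_cv_target across-sample CV% the stable housekeeping
#'   gene is tuned to (default 9).
#' @param planted_targets symbols of the overexpressed target GPCRs.
#' @param target_multiplier cancer-state overexpression multiplier applied to
#'   the planted targets' healthy baseline (default 180).
#' @param penetrance fraction of cancer samples in which a planted target is
#'   in the overexpressed state (default 0.9).
#' @param healthy_baseline_quantile quantile of the GPCR abundance
#'   distribution at which planted targets sit in healthy tissue
#'   (default 0.25).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genes = 2000L,
                           gpcr_count = 200L,
                           cancer_cohort_sizes = c(cohortA = 77L, cohortB = 9L,
                                                   cohortC = 10L, cohortD = 20L,
                                                   cohortE = 35L),
                           healthy_tissues = rep(c("peritoneal", "fallopian",
                                                   "ovarian_surface"), each = 3L),
                           library_size_lognorm = c(meanlog = log(2e6), sdlog = 0.35),
                           dispersion = 0.2,
                           housekeeping_cv_target = 9,
                           planted_targets = c("ADGRF5", "ADGRG1", "ADRA2C",
                                               "CELSR1", "CELSR2", "CXCR4",
                                               "F2R", "GPR183", "LGR6",
                                               "LPAR3", "PTAFR", "PTH2R",
                                               "S1PR2"),
                           target_multiplier = 180,
                           penetrance = 0.9,
                           healthy_baseline_quantile = 0.25) {
  stopifnot(n_genes >= gpcr_count + 15L, gpcr_count >= length(planted_targets),
            dispersion > 0, penetrance >= 0, penetrance <= 1,
            target_multiplier > 0,
            healthy_baseline_quantile > 0, healthy_baseline_quantile < 1,
            all(cancer_cohort_sizes >= 2L), length(healthy_tissues) >= 2L)
  if (penetrance > 1) stop("penetrance cannot exceed 1")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gpcr_count = as.integer(gpcr_count),
                 cancer_cohort_sizes = cancer_cohort_sizes,
                 healthy_tissues = healthy_tissues,
                 library_size_lognorm = library_size_lognorm,
                 dispersion = dispersion,
                 housekeeping_cv_target = housekeeping_cv_target,
                 planted_targets = planted_targets,
                 target_multiplier = target_multiplier,
                 penetrance = penetrance,
                 healthy_baseline_quantile = healthy_baseline_quantile),
            class = "synthetic_spec")
}

# Abundance scale: per-gene expression level x_g on an RPKM-like scale
# (expected counts proportional to x_g * length_bp). Background genes are
# lognormal around 5; GPCR genes lognormal around 0.5 (low-to-moderate bias);
# housekeeping candidates are fixed high with per-gene dispersions tuned to
# their target CVs.
.sim_gene_table <- function(spec) {
  hk <- hk_candidates()
  planted <- spec$planted_targets
  n_other_gpcr <- spec$gpcr_count - length(planted)
  n_bg <- spec$n_genes - spec$gpcr_count - length(hk)
  symbols <- c(planted,
               sprintf("GPCR%04d", seq_len(n_other_gpcr)),
               hk,
               sprintf("GENE%05d", seq_len(n_bg)))
  is_gpcr <- c(rep(TRUE, spec$gpcr_count), rep(FALSE, length(hk) + n_bg))
  length_bp <- pmax(200L, as.integer(round(stats::rlnorm(spec$n_genes,
                                                         log(1800), 0.5))))
  # healthy-state abundance
  x <- numeric(spec$n_genes)
  gpcr_meanlog <- log(0.5); gpcr_sdlog <- 1.2
  x[seq_along(planted)] <- stats::qlnorm(spec$healthy_baseline_quantile,
                                         gpcr_meanlog, gpcr_sdlog)
  x[length(planted) + seq_len(n_other_gpcr)] <-
    stats::rlnorm(n_other_gpcr, gpcr_meanlog, gpcr_sdlog)
  hk_levels <- stats::setNames(seq(30, 100, length.out = length(hk)), sort(hk))
  hk_levels["SDHA"] <- 60
  x[spec$gpcr_count + seq_along(hk)] <- hk_levels[hk]
  x[spec$gpcr_count + length(hk) + seq_len(n_bg)] <- stats::rlnorm(n_bg, log(5), 1.5)
  # ~8% of background genes are near-silent so the pre-normalization filter
  # has genuine work to do (CPM 0 in most samples)
  silent <- spec$gpcr_count + length(hk) +
    which(stats::runif(n_bg) < 0.08)
  x[silent] <- x[silent] * 1e-4
  # per-gene dispersion: stable housekeeping panel, noisy everything else
  phi <- rep(spec$dispersion, spec$n_genes)
  hk_cv <- stats::setNames(stats::runif(length(hk), 0.25, 0.45), hk)
  hk_cv["SDHA"] <- spec$housekeeping_cv_target / 100
  hk_cv["GAPDH"] <- 0.223
  hk_cv["ACTB"] <- 0.288
  phi[spec$gpcr_count + seq_along(hk)] <- hk_cv[hk]^2
  data.frame(symbol = symbols, length_bp = length_bp, is_gpcr = is_gpcr,
             x_healthy = x, phi = phi, stringsAsFactors = FALSE)
}

#' Simulate a multi-cohort collection
#'
#' Draws, for each cohort, negative-binomial counts with per-sample expected
#' counts proportional to gene abundance times gene length, scaled to the
#' sample's lognormal library size. Cancer cohorts receive mild per-cohort
#' abundance noise (lognormal, sd 0.25 on the log scale) plus the planted
#' overexpression: in each cancer sample each planted target is, with
#' probability `penetrance`, in the overexpressed state
#' (`target_multiplier` times its healthy baseline).
#'
#' @param spec a [synthetic_spec()].
#' @return A list of class `synthetic_collection` with `cohorts` (named list
#'   of [count_matrix()], cancer cohorts first, then `"healthy"`),
#'   `annotation` ([gene_annotation()]), `meta` (sample metadata data.frame)
#'   and `truth` (planted symbols, multiplier, penetrance).
#' @export
simulate_collection <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- .sim_gene_table(spec)
  ann <- suppressMessages(
    gene_annotation(genes[c("symbol", "length_bp", "is_gpcr")]))
  planted_idx <- match(spec$planted_targets, genes$symbol)

  sim_cohort <- function(cohort_id, n, cancer) {
    x_cohort <- genes$x_healthy
    if (cancer)  # mild cohort-level abundance shift, housekeeping kept stable
      x_cohort <- x_cohort * ifelse(genes$symbol %in% hk_candidates(), 1,
                                    stats::rlnorm(nrow(genes), 0, 0.25))
    libs <- stats::rlnorm(n, spec$library_size_lognorm[["meanlog"]],
                          spec$library_size_lognorm[["sdlog"]])
    counts <- matrix(0L, nrow(genes), n,
                     dimnames = list(genes$symbol,
                                     sprintf("%s_S%02d", cohort_id, seq_len(n))))
    for (s in seq_len(n)) {
      xs <- x_cohort
      if (cancer) {
        boosted <- stats::runif(length(planted_idx)) < spec$penetrance
        xs[planted_idx] <- genes$x_healthy[planted_idx] *
          ifelse(boosted, spec$target_multiplier, 1)
      }
      w <- xs * genes$length_bp
      mu <- w / sum(w) * libs[s]
      counts[, s] <- stats::rnbinom(nrow(genes), mu = mu, size = 1 / genes$phi)
    }
    count_matrix(counts, cohort_id)
  }

  cohorts <- list()
  meta <- list()
  groups <- list(cohortA = c("Pre-chemo", "Post-chemo"),
                 cohortB = c("Primary", "Omentum", "Effusion"),
                 cohortC = "Primary", cohortD = c("Primary", "Metastatic"),
                 cohortE = c("Pre-NACT", "Post-NACT"))
  for (cid in names(spec$cancer_cohort_sizes)) {
    n <- spec$cancer_cohort_sizes[[cid]]
    cohorts[[cid]] <- sim_cohort(cid, n, cancer = TRUE)
    gset <- groups[[cid]] %||% "Primary"
    meta[[cid]] <- data.frame(
      sample_id = colnames(cohorts[[cid]]$counts), cohort_id = cid,
      condition = "cancer",
      group = rep_len(gset, n),
      treatment = NA_character_, extraction = "sections",
      tissue = NA_character_, stringsAsFactors = FALSE)
  }
  nh <- length(spec$healthy_tissues)
  cohorts[["healthy"]] <- sim_cohort("healthy", nh, cancer = FALSE)
  meta[["healthy"]] <- data.frame(
    sample_id = colnames(cohorts[["healthy"]]$counts), cohort_id = "healthy",
    condition = "healthy", group = "Healthy", treatment = NA_character_,
    extraction = "sections", tissue = spec$healthy_tissues,
    stringsAsFactors = FALSE)
  meta <- do.call(rbind, c(meta, list(make.row.names = FALSE)))

  structure(list(cohorts = cohorts, annotation = ann, meta = meta,
                 truth = list(planted = sort(spec$planted_targets),
                              multiplier = spec$target_multiplier,
                              penetrance = spec$penetrance),
                 spec = spec),
            class = "synthetic_collection")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_collection <- function(x, ...) {
  sizes <- vapply(x$cohorts, function(m) ncol(m$counts), integer(1))
  cat("<synthetic_collection> ", length(x$cohorts), " cohorts (",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), "); ",
      nrow(x$annotation), " genes, ", sum(x$annotation$is_gpcr),
      " GPCRs, ", length(x$truth$planted), " planted targets\n", sep = "")
  invisible(x)
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct values are drawn uniformly from the stable band a good
#' housekeeping gene shows (default 20-23 cycles); each target gene gets a
#' per-gene mean delta-Ct, with per-sample Gaussian spread around it. A
#' configurable fraction of target cells is pushed above the detection limit.
#' Exact per-gene delta-Ct values can be planted instead via
#' `planted_delta_ct`.
#'
#' @param targets character vector of target gene symbols.
#' @param n_samples number of samples (default 10).
#' @param seed RNG seed.
#' @param reference_gene reference symbol (default `"SDHA"`).
#' @param ct_ref_range uniform band for the reference Ct, cycles.
#' @param delta_ct_mean_range per-gene mean delta-Ct drawn uniformly from this
#'   range (default 4-11 cycles).
#' @param delta_ct_sd per-sample spread around the gene mean (default 1.5).
#' @param nondetect_fraction fraction of target cells set above the detection
#'   limit (default 0.05).
#' @param detection_limit cycles (default 35).
#' @param planted_delta_ct optional numeric vector (length = targets) of exact
#'   delta-Ct values applied to every sample; overrides the random draws.
#' @return A [ct_table()].
#' @export
simulate_ct_table <- function(targets, n_samples = 10L, seed = 1L,
                              reference_gene = "SDHA",
                              ct_ref_range = c(20, 23),
                              delta_ct_mean_range = c(4, 11),
                              delta_ct_sd = 1.5,
                              nondetect_fraction = 0.05,
                              detection_limit = 35,
                              planted_delta_ct = NULL) {
  set.seed(seed)
  samples <- sprintf("P%02d", seq_len(n_samples))
  refct <- stats::runif(n_samples, ct_ref_range[1], ct_ref_range[2])
  if (is.null(planted_delta_ct)) {
    mu <- stats::runif(length(targets), delta_ct_mean_range[1],
                       delta_ct_mean_range[2])
    dct <- matrix(stats::rnorm(length(targets) * n_samples, mean = mu,
                               sd = delta_ct_sd),
                  length(targets), n_samples)
    dct <- pmax(dct, 0)
    nd <- stats::runif(length(dct)) < nondetect_fraction
  } else {
    stopifnot(length(planted_delta_ct) == length(targets))
    dct <- matrix(planted_delta_ct, length(targets), n_samples)
    nd <- rep(FALSE, length(dct))
  }
  ct <- sweep(dct, 2L, refct, "+")
  ct[nd] <- detection_limit + 1 + stats::runif(sum(nd), 0, 5)
  ct <- rbind(ct, refct)
  dimnames(ct) <- list(c(targets, reference_gene), samples)
  ct_table(ct, reference_gene = reference_gene,
           detection_limit = detection_limit)
}
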