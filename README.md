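# gpcrhunt

Screening bulk RNA-seq cohorts for overexpressed G-protein coupled receptors
(GPCRs) that could serve as cell-surface targets for ligand-decorated
nanomedicines — with high-grade serous ovarian cancer as the motivating
setting. The package is aimed at computational biologists who have raw count
matrices from several independent cohorts (e.g. GEO studies processed with a
uniform quantification pipeline) plus one healthy-tissue cohort, and who want
a reproducible, threshold-based target screen rather than an inferential
differential-expression analysis.

## The method

Starting from per-cohort gene × sample raw counts:

1. **Normalization (from first principles).** Genes with no expression
   (CPM = 0) in more than 70 % of a cohort's samples are discarded
   (a CPM > 1 dialect is also available). Samples are scaled with
   trimmed-mean-of-M-values (TMM) factors — for sample *k* versus a
   data-selected reference sample *r*, over genes positive in both,

   M<sub>g</sub> = log₂((y<sub>gk</sub>/N<sub>k</sub>)/(y<sub>gr</sub>/N<sub>r</sub>)),  A<sub>g</sub> = ½·log₂((y<sub>gk</sub>/N<sub>k</sub>)·(y<sub>gr</sub>/N<sub>r</sub>)),

   doubly trimmed (30 % on M, 5 % on A) and averaged with
   inverse-asymptotic-variance weights: f<sub>k</sub> = 2^(Σw·M / Σw),
   rescaled to geometric mean 1. Counts are then converted to
   RPKM = y·10⁹ / (L·N·f) with gene length L and effective library size N·f.
2. **Reference gene.** Among 15 housekeeping candidates, the gene with the
   lowest coefficient of variation (CV% = 100·SD/mean) across the healthy
   cohort is chosen as internal standard (typically *SDHA*); all expression is
   then re-expressed as a percentage of it.
3. **Selection cascade.** A GPCR is *expressed* in a cohort when it reaches
   ≥ 40 % of the reference gene in ≥ 30 % of samples; genes expressed in ≥ 3
   cohorts are *preselected*; a preselected gene is *retained* when its
   pooled-cancer expression exceeds mean + 2·SD of the healthy (peritoneal)
   baseline in ≥ 65 % of the pooled samples.
4. **Clustering.** Pooled samples are hierarchically clustered (Ward/Euclidean
   by default) on the final panel, expressed as % of the reference gene.
5. **qPCR validation.** ΔCt = Ct(target) − Ct(reference); Ct > 35 cycles is
   below the detection limit; fold-reduction versus the reference is
   (1+E)^ΔCt (2^ΔCt at 100 % primer efficiency).

A seeded negative-binomial simulator (`simulate_collection()`) generates
multi-cohort collections with planted overexpressed targets, so the whole
cascade is testable end to end without any download.

## Worked example

```r
library(gpcrhunt)

sim <- simulate_collection(synthetic_spec(seed = 42))
scr <- gpcr_screen(sim$cohorts[names(sim$cohorts) != "healthy"],
                   sim$cohorts$healthy, sim$annotation, sim$meta,
                   verbose = FALSE)
scr
#> GPCR target screen
#>   reference gene: SDHA (CV 7.2%)
#>   cohorts screened: 5
#>   expressed GPCRs (union): 14  ->  preselected: 13  ->  final targets: 13
#>   panel: ADGRF5, ADGRG1, ADRA2C, CELSR1, CELSR2, CXCR4, F2R, GPR183, LGR6, LPAR3, PTAFR, PTH2R, S1PR2
#>   clustering: 12 clusters (sizes 15, 22, 9, 12, 8, 12, 20, 14, 12, 18, 6, 3)

identical(scr$report$final_targets, sim$truth$planted)
#> [1] TRUE
```

The printout reads as the selection funnel: five cancer cohorts (77/9/10/20/35
samples, 151 pooled) were normalized, *SDHA* was picked as the most stable
housekeeping gene on the 9-sample healthy cohort, 14 GPCRs were called
expressed in at least one cohort, 13 of them in at least three cohorts, all
13 survived the healthy-baseline filter, and the pooled samples split into 12
clusters on that panel. The final
line confirms that the recovered panel equals the simulator's planted truth.

For qPCR validation data:

```r
ct <- simulate_ct_table(scr$report$final_targets, n_samples = 10, seed = 1)
res <- delta_ct(ct)
res
#> <delta_ct_result> 13 targets x 10 samples vs SDHA
#>   detected: 127/130 cells
#>   delta-Ct range 2.96-12.79 (7.81- to 7081-fold below reference)
```

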