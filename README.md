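# hifbind

Isoform-specific transcription-factor binding analysis and prognostic
modeling, built around the HIF-1α / HIF-2α system in clear cell renal
carcinoma (CCRC).

CCRC cells are typically VHL-defective, leaving hypoxia-inducible factor
(HIF) constitutively active. The two alpha isoforms dimerize with the same
HIF-1β partner and bind the same RCGTG core, yet drive opposite effects on
tumor growth. Answering *which sites are isoform-specific, what sequence
features distinguish them, and whether the genes they control carry
prognostic signal* requires a chain of bespoke computations that this
package implements as a tested, reusable pipeline:

- **Peak processing** — dual-caller consensus intervals
  (`consensus_peaks`), RPKM signal (`compute_rpkm`), quantitative
  filtering at the 99.99th percentile of random background regions
  (`background_threshold`, `filter_peaks`), log-scale scatter/equity
  summaries (`signal_scatter`) and an SVD-based PCA biplot (`pca_biplot`).
- **Site annotation** — nearest-TSS links and signed distances
  (`nearest_tss`, `tss_histogram`), gene-class breakdowns
  (`class_breakdown`), inclusive ≥3-fold isoform classification with a
  pseudocount of 1 (`classify_isoform_specific`), 10-kb gene capture
  (`genes_within`).
- **Motif scanning** — the normalized likelihood-ratio PWM score

  ```
  NLR_j = (1/L) * sum_i PWM(b_{j+i}, i) / B(b_{j+i}),    PNLR = max_j NLR_j
  ```

  over summit ± 150 bp windows and both strands (`nlr_profile`, `pnlr`,
  `scan_regions`), with a LOO-CV smoothing-spline trend along a signal
  ranking (`motif_trend`) and a Mann-Whitney differential test between
  site sets (`differential_motif_test`).
- **Expression** — per-gene negative-binomial likelihood-ratio tests with
  median-of-ratios normalization (`nb_two_group_lrt`,
  `size_factors_median_ratio`), and the signed ranking statistic
  `pi = log2FC * (-log10 p)` (`rank_statistic`, `build_ranking`).
- **Enrichment** — pre-ranked GSEA with a weighted running-sum score and a
  gene-set permutation null (`enrichment_score`, `gsea_permutation`,
  `two_tail_report`).
- **Outcome** — the 0–4 clinical prognostic score (`prognostic_score`),
  Kaplan-Meier and Cox machinery (`km_estimator`, `cox_fit`), and a
  supervised-PCA gene predictor with univariate Cox screening, unit-norm
  SVD weights, leave-one-out cross-validation and median-split evaluation
  (`univariate_screen`, `spca_fit`, `loo_cv`, `median_split_eval`).
- **Synthetic data** — `simulation_config` + `simulate_*` generate
  annotation, binding sites, signal, motif-planted sequences, counts and a
  survival cohort with known planted structure, so the whole pipeline is
  testable offline. `hif_cli()` exposes the stages as subcommands.

## Worked example

```r
library(hifbind)
cfg <- simulation_config(seed = 42, n_genes = 800, n_sites_isoform1 = 120,
                         n_sites_isoform2 = 120, n_sites_shared = 160,
                         n_patients = 120)
ann <- simulate_annotation(cfg)
bnd <- simulate_binding(cfg, ann)

## 1. consensus peaks from the two jittered caller outputs
nrow(consensus_peaks(bnd$caller_a, bnd$caller_b))
#> [1] 387

## 2. isoform-specific classification (pseudocounted >= 3-fold rule)
table(classify_isoform_specific(bnd$signal, "H1A", "H2A")$call)
#> isoform1_specific isoform2_specific            shared
#>               120               120               160

## 3. AP-1 motif scores differ between the isoform-specific site sets
jaspar <- system.file("extdata", "synthetic_jaspar_motifs.txt", package = "hifbind")
ap1 <- pwm_from_counts(read_jaspar_pwm(jaspar, "SYN_AP1.1"))
bg  <- background_from_regions(bnd$sequences)
sc  <- scan_regions(bnd$sequences, ap1, bg)
i2  <- bnd$labels == "isoform2_specific"
differential_motif_test(sc$log_pnlr[i2], sc$log_pnlr[!i2])[c("pvalue", "direction")]
#> $pvalue
#> [1] 0.04299451
#> $direction
#> [1] "A_higher"

## 4. DE -> ranking -> GSEA: genes near isoform-1 sites are up-regulated
cnt <- simulate_counts(cfg, ann, bnd)
de  <- nb_two_group_lrt(cnt$counts, cnt$groups)
rk  <- build_ranking(de)
gs  <- unique(bnd$host_gene[bnd$labels == "isoform1_specific"])
gsea_permutation(rk, gs, n_perm = 1000, seed = 42)
#> enrichment_result: ES=0.941 NES=1.777 p=0.000999 (1000 permutations)

## 5. SPCA survival predictor, leave-one-out cross-validated
coh <- simulate_cohort(cfg, sprintf("g%02d", 1:30))
cv  <- loo_cv(coh$expression, coh$clinical$time, coh$clinical$event)
ev  <- median_split_eval(cv$scores, coh$clinical$time, coh$clinical$event)
c(HR = ev$fit$hazard_ratio, p = ev$fit$pvalue)
#>           HR            p
#> 4.705754e+00 3.393237e-06
```

Reading the numbers: 387 consensus regions survive intersecting the two
caller outputs (adjacent sites merge); the classifier recovers the planted
120/120/160 design exactly; AP-1 scores are shifted higher at
isoform-2-specific sites (at this small scale, modestly: p ≈ 0.04); genes
hosting isoform-1 sites are strongly enriched among up-regulated genes
(ES 0.94, permutation p ≈ 1e-3, the floor for 1000 permutations); and the
cross-validated risk score splits the cohort into groups with a hazard
ratio ≈ 4.7.

The motif file shipped under `inst/extdata/` contains *synthetic* HRE-like
and AP-1-like matrices (labeled as such); supply real database matrices to
`read_jaspar_pwm()` for real analyses.

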