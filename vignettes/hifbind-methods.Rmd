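---
title: "Methods and modeling choices in hifbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in hifbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Clear cell renal carcinoma is typically VHL-defective, so hypoxia-inducible
factor (HIF) is constitutively active. The two alpha isoforms, HIF-1α and
HIF-2α, dimerize with the shared HIF-1β subunit, recognize the same RCGTG
hypoxia-response-element (HRE) core, and yet drive opposite effects on tumor
growth. `hifbind` packages the quantitative machinery needed to dissect that
contrast from genomics data: which genomic sites bind one isoform and not the
other, how motif composition changes across sites, how isoform-specific
binding couples to transcriptional output, and whether genes near
isoform-specific sites carry prognostic information in a patient cohort.

The package has three layers: (i) ChIP-seq peak processing (consensus
calling, RPKM signal, background-percentile filtering, PCA, isoform
classification, TSS annotation); (ii) sequence analysis (a normalized
likelihood-ratio PWM scanner with spline trends and a rank-based
differential test); (iii) expression and outcome (negative-binomial LRT
differential expression, a signed ranking statistic feeding pre-ranked GSEA,
a clinical stratification score, and a supervised-PCA survival predictor
validated by leave-one-out cross-validation). A synthetic-data module
generates all the inputs with known planted structure, so every stage is
testable offline.

# Peak processing

**Consensus peaks.** Two peak callers with different models (in the original
workflow, a tree-shape method and a model-based method) disagree at the
margins. `consensus_peaks()` keeps only base pairs covered by *both* interval
sets — the intersection span, not the union — because the downstream summit
convention (interval midpoint) is stable under intersection and the
conservative choice costs only peak width, not peak count, at realistic
jitter.

**Quantitative background filter.** Peaks are kept when the total signal
under the peak reaches the upper 99.99th percentile of a large set of random
non-overlapping background regions (`background_threshold()` with tail
probability `p = 1e-4`). The threshold is the smallest background value such
that at most `floor(n * p)` background values sit at or above it — a
nearest-rank rule with no interpolation, chosen so that with one million
background regions almost exactly 100 pass their own filter, which is the
calibration the tests assert. The filter is applied per condition; whether
the original analysis pooled conditions is not documented, and per-condition
filtering is the conservative reading.

**Log scale and PCA.** Scatter summaries and the PCA biplot work on
`log2(x + 1)` signal: ChIP enrichment is right-skewed over decades, and the
`+1` keeps zero-signal regions defined. `pca_biplot()` centers each
condition and takes the SVD; site scores are `U D`, condition loadings are
the right singular vectors, and signs are fixed by making each component's
largest-magnitude loading positive (singular vectors are sign-ambiguous and
an arbitrary flip would make test expectations and plots unstable).

**Isoform classification.** A site is isoform-1-specific when
`(v1 + 1) / (v2 + 1) >= 3`, isoform-2-specific when the ratio is `<= 1/3`,
shared otherwise. The pseudocount of 1 RPKM keeps unbound sites defined and
shrinks ratios of near-zero signals toward 1, so noise at unbound sites does
not masquerade as specificity. The 3-fold boundary is inclusive ("at least
3-fold"), and the rule is exactly antisymmetric under swapping the two
conditions.

# The normalized likelihood-ratio scanner

For a position weight matrix of length $L$ with column probabilities
$\mathrm{PWM}(b, i)$ and background base weights $B(b)$, the per-window
statistic is the *arithmetic mean* of per-position probability ratios,

$$\mathrm{NLR}_j = \frac{1}{L} \sum_{i=1}^{L}
  \frac{\mathrm{PWM}(b_{j+i}, i)}{B(b_{j+i})},$$

and the region score is the maximum over all windows (and, by default, both
strands), reported as `log2(pnlr)`. The mean form is what the source
formula states, even though the textbook likelihood ratio is a *product* of
per-position ratios; the two disagree (the mean is dominated by the best
positions, the product by the worst). Both are implemented — `form = "mean"`
(default) and `form = "product"`, the latter as the geometric mean so the
two forms share a scale — and the scanner is verified against an
independent brute-force double loop to 1e-12 either way. Windows containing
N (e.g. repeat-masked bases) score 0 and are flagged rather than silently
skipped.

Defaults worth knowing: PWM pseudocount 0.25 per cell on the counts scale
(perturbs a 20-observation JASPAR-style column by ~1%, while guaranteeing
positive entries), background pseudocount 1 per base, scan window = summit
± 150 bp. Ties in the maximum resolve to the smallest offset, then the
forward strand, so results are reproducible to the byte.

The bundled motif file (`inst/extdata/synthetic_jaspar_motifs.txt`)
contains *synthetic stand-ins* — an RCGTG-core HRE-like matrix and a
TGACTCA AP-1-like matrix in the 2009-era JASPAR flat format. They are
constructed, not retrieved from a database, and are labeled as such; real
analyses should supply real matrices through `read_jaspar_pwm()`.

**Trend and differential analyses.** `motif_trend()` ranks regions by a
signal (HIF-1β RPKM in the motivating design), then fits a cubic smoothing
spline of `log2(pnlr)` on rank with the smoothing parameter selected by
ordinary leave-one-out cross-validation — R's `smooth.spline(cv = TRUE)`,
which is the exact implementation the original figures cite, and the reason
this package does not substitute its own smoothing-parameter grid.
`differential_motif_test()` compares two sets of region scores with a
two-sided Mann-Whitney test: the source reports a significance level
without naming a test, and a rank test is the defensible default for
heavy-tailed maximum scores. This substitution is deliberate and documented.

# Differential expression and ranking

`nb_two_group_lrt()` is a deliberately plain per-gene negative-binomial
likelihood ratio test: within each model (two group means vs one shared
mean) the gene's dispersion is profiled by maximum likelihood (alternating
closed-form/Newton mean updates with `MASS::theta.ml`), and twice the
log-likelihood difference is referred to chi-square with 1 df. Size factors
default to the median-of-ratios estimator scaled to geometric mean 1.
There is no dispersion moderation across genes — this stage replicates the
`glm.nb`-style analysis used for the cohort arm, not an empirical-Bayes
method — and that has a measurable cost: with 3 + 3 replicates and true
dispersion 0.1, the test's empirical type-I error at nominal 0.05 is about
0.12, because the per-gene dispersion estimate at 4 residual degrees of
freedom is extremely variable and the chi-square reference does not account
for it. We verified that the inflation is estimator *variance*, not bias:
Cox-Reid-adjusted and exact conditional-ML dispersion estimators are nearly
unbiased here and calibrate no better, while an oracle given the true
dispersion calibrates almost exactly (0.0525). The corresponding acceptance
check asserts the idealized band [0.03, 0.07] and is expected to fail; it
is kept failing rather than weakened, because the discrepancy is a real
property of the method. At moderate replicate numbers, or with externally
moderated dispersions, calibration is honest. Fold-change estimation is
unbiased throughout (mean recovered log2FC of planted 2× effects is within
±0.3 of 1).

Genes are ranked for enrichment analysis by the signed statistic
$\pi_i = \varphi_i \cdot (-\log_{10} pv_i)$ with $\varphi_i$ the log2
fold-change; p-values of exactly 0 are clamped to 1e-300 to keep $\pi$
finite. The ranking consumes any table with `gene`, `log2fc`, `pvalue`
columns, so DE results computed elsewhere (e.g. by DESeq2) plug in
directly.

# Pre-ranked GSEA

`enrichment_score()` is the weighted Kolmogorov-Smirnov-style running sum:
hits advance by $|\pi|^p / \sum_{hits} |\pi|^p$ (default $p = 1$, the
"weighted" statistic), misses retreat by $1/(N-k)$, and the enrichment
score is the extremum of largest magnitude with its sign. Because the
input is pre-ranked, sample-label permutation is unavailable; the null is
ES of random same-size gene sets drawn from the ranking universe
(`gsea_permutation()`, default 10000 permutations).

The p-value counts permutations whose $|ES|$ reaches the observed $|ES|$,
with the add-one correction so p is never 0. A direction-restricted count
against the full permutation denominator — one literal reading of the
source description — cannot be uniform under the null (it is confined to
roughly (0, 0.5]), so the two-sided count is used; it calibrates to
Uniform(0,1) in the acceptance tests, and directional statements
("enriched among upregulated but not downregulated genes") are provided by
`two_tail_report()`, which evaluates both ends of the ranking explicitly.

# Survival arm

**Clinical stratification.** `prognostic_score()` adds one point for each
of: age > 60, stage 3-4, metastasis, deceased; 0-1 is "good", 2-4 "poor"
prognosis. This is implemented exactly as specified, including the
deceased indicator — which overlaps the survival outcome. Using these
groups for expression contrasts is fine; using them as a covariate in a
survival model of the same patients would be circular, and the
documentation says so prominently rather than silently "fixing" the score.

**Supervised PCA predictor.** Candidate genes (in the motivating design,
genes within 10 kb of isoform-specific sites) are standardized and screened
by univariate Cox proportional-hazards significance (Wald p < 0.05, Efron
ties). The screened block's first right singular vector gives unit-norm
gene weights; each patient's risk score is the projection onto those
weights, with the sign oriented so higher score means higher hazard
(singular vectors are sign-ambiguous, so an explicit convention is
required). Standardization before both screen and SVD is a documented
choice: expression spans decades and an unscaled SVD would let a few
high-variance genes own the component.

`loo_cv()` repeats screen + fit on every leave-one-out fold and projects
the held-out patient with the fold's own centering, scale and weights —
no information leaks from the held-out patient into its score. Folds whose
screen returns fewer than two genes produce `NA` scores (logged); under a
global null this is the *common* outcome, and the evaluation treats an
unbuildable predictor as a non-rejection. Final evaluation splits patients
at the median out-of-fold score (ties to the low group) and fits Cox on the
binary indicator, pooling all out-of-fold scores — the "assessed similar to
univariate analysis" reading. Inside the fold loop, untied data are fitted
by a vectorized Newton solver on the partial likelihood that is exactly
`coxph` for untied times (verified to 1e-6); tied data fall back to
`survival::coxph` per gene.

# The synthetic world

`simulation_config()` fixes one stated world; tests and acceptance checks
never tune it after seeing results. Choices, with reasons:

- **Sites and signal**: a few hundred sites per class on a single virtual
  chromosome (nothing downstream needs more chromosomes); log-normal RPKM
  (meanlog 3, sdlog 1), because enrichment signal is right-skewed over
  decades. Isoform-specific sites are drawn with the pseudocounted fold gap
  *enforced* at ≥ 3, so classifier recovery must be exact, not approximate;
  shared sites are confined within 3-fold.
- **HIF-1β coupling** 0.8 on the log scale by default (strong but
  imperfect co-occupancy of the obligate dimerization partner); coupling 1
  gives exact proportionality, which the tests use as a closed-form case.
- **Motif planting**: consensus strings (TGACTCA for AP-1; the extended
  TRCGTGC consensus for the HRE — a bare 5-mer RCGTG occurs by chance in
  most 301-bp windows and would be invisible to a max-score scanner) at rate
  `base + slope * f(rank)` with base 0.25 and slope 0.5 — strong enough
  that 250 sites per class separate clearly, weak enough that planting is
  probabilistic. Slope 0 is the exchangeable null used to check that the
  trend and differential tests do not invent structure. PWM-weighted
  sampling of planted instances is deliberately not modeled; consensus
  planting is sufficient for recoverability and keeps the planted truth
  unambiguous.
- **Counts**: NB with gene-wise theta ~ lognormal(log 10, 0.3) (dispersion
  near 0.1, typical for bulk RNA-seq), 3 + 3 replicates, ~10% of genes DE,
  positive fold changes at genes hosting isoform-1 sites (binding coupled
  to activation, not repression).
- **Cohort**: 415 patients so each leave-one-out fold trains on exactly
  414; exponential survival with baseline median 1000 days; log hazard
  ratio 1 per latent-factor unit; independent exponential censoring tuned
  to a 60% censored fraction, as in typical registry cohorts; age, stage
  and metastasis drawn so the 0-4 clinical score correlates with the
  latent factor; the deceased flag equals observed death, as a registry
  snapshot would record it.

What the generator does *not* emulate: real genome sequence composition,
repeat structure, read-level noise, multiple chromosomes, copy-number
effects, or correlated gene-gene expression beyond the single latent
factor. A green test therefore establishes that the algorithms recover the
structure they claim to recover under their stated model — not that the
biological conclusions of any particular dataset are correct.

# Numerical conventions

- Coordinates are 0-based half-open (BED) everywhere internally; 1-based
  sources must be converted at the reader.
- Missing summits default to the interval midpoint.
- Quantiles are nearest-rank; no interpolation anywhere in the filter.
- Smoothing-spline ties in ranks cannot occur (ranks are distinct by
  construction).
- The LRT statistic is clamped at 0; p-values of exactly 0 are clamped to
  1e-300; theta is confined to [1e-3, 1e8].
- All stochastic stages take explicit integer seeds and are byte-identical
  under them; the simulation derives independent per-stage streams from
  `seed + stage offset`.

# Known limitations

- The per-gene NB LRT is anti-conservative at very small replicate numbers
  (see above); its acceptance band is intentionally left failing.
- The final significance of the cross-validated predictor is itself mildly
  anti-conservative. Out-of-fold scores are honest per patient, but any
  two folds share all but two patients, the weight orientation uses
  training survival, and the pooled Cox fit treats the resulting
  correlated scores as a fixed independent covariate — the documented
  anti-conservatism of "pre-validation" style evaluation. Measured on
  null cohorts (no survival-expression coupling, 415 patients, 40
  candidate genes), the rejection rate of the HR > 1, p < 0.05 rule is
  about 0.15 over 60 simulated cohorts; the corresponding acceptance
  bound (0.10) is intentionally left failing. A permutation reference for
  the final p-value would repair the calibration at the cost of stepping
  outside the evaluated design.
- The mean-form NLR is not a likelihood ratio in the probabilistic sense;
  cross-study comparisons should state which form was used.
- The prognostic stratification score contains the outcome by
  construction; it exists for expression contrasts.
- `consensus_peaks()` intersects merged interval sets; callers that emit
  heavily fragmented peaks will see narrower consensus regions than a
  union-based rule would give.
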