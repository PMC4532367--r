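## Synthetic-data generator: fixtures with the statistical structure the
## analysis assumes, so every stage is testable without external data.
##
## The generator states one world and sticks to it: two partially
## overlapping binding-site sets whose signal differs by an enforced
## >= 3-fold gap, HIF-1beta signal co-varying with the alpha-subunit
## signal, motif planting whose probability moves with the HIF-1beta rank,
## negative-binomial expression coupled to isoform-1 binding, and a
## patient cohort whose expression and clinical covariates are driven by a
## latent prognostic factor with censored exponential survival.
##
## Each stage draws from its own seeded stream (config$seed + stage
## offset), so stages are individually reproducible and identical
## seed + config gives byte-identical outputs.

GENE_CLASSES <- c("protein_coding", "lncRNA", "antisense", "other")

#' Build a validated simulation configuration
#'
#' Defaults describe a desk-scale cut of the cell-line + cohort design the
#' pipeline targets: a few hundred binding sites per isoform class,
#' log-normal RPKM-like signal, 2000 genes with 3 + 3 replicate counts,
#' and a 415-patient cohort (matching the 414-training-patient
#' leave-one-out design) with roughly 60% censoring as in typical renal
#' carcinoma registry data.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of annotated genes.
#' @param class_proportions Named simplex over
#'   `protein_coding, lncRNA, antisense, other` (subset allowed); must sum
#'   to 1. Default plants 68% protein-coding.
#' @param n_sites_isoform1,n_sites_isoform2,n_sites_shared Site counts per
#'   binding class.
#' @param signal_meanlog,signal_sdlog Log-normal parameters of the
#'   per-condition signal (RPKM scale).
#' @param hif1b_coupling Correlation (in `[0, 1]`) between the alpha
#'   subunit and HIF-1beta signal at a site, on the log scale; 1 means the
#'   two signals are identical up to scale.
#' @param motif_base_rate,motif_slope Motif planting probability model:
#'   `base + slope * f(rank)` (clamped to `[0, 1]`), where `f` falls from
#'   1 to 0 as the HIF-1beta rank improves for the AP-1 motif (isoform-2
#'   sites) and rises for the HRE core (all sites). `motif_slope = 0`
#'   makes planting rank- and class-independent.
#' @param n_patients Cohort size (>= 3).
#' @param latent_effect Log hazard ratio per unit of the latent prognostic
#'   factor.
#' @param censoring_rate Fraction of patients censored (in `[0, 1)`), via
#'   an independent exponential censoring time.
#' @param de_fraction Fraction of genes differentially expressed.
#' @param de_lfc_scale Scale of planted log2 fold-changes (0 = global null).
#' @param chrom_length Virtual chromosome length; default `5000 * n_genes`.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_genes = 2000,
                              class_proportions = c(protein_coding = 0.68,
                                                    lncRNA = 0.14,
                                                    antisense = 0.08,
                                                    other = 0.10),
                              n_sites_isoform1 = 300,
                              n_sites_isoform2 = 300,
                              n_sites_shared = 400,
                              signal_meanlog = 3,
                              signal_sdlog = 1,
                              hif1b_coupling = 0.8,
                              motif_base_rate = 0.25,
                              motif_slope = 0.5,
                              n_patients = 415,
                              latent_effect = 1,
                              censoring_rate = 0.6,
                              de_fraction = 0.1,
                              de_lfc_scale = 1,
                              chrom_length = NULL) {
  if (!is_count(n_genes)) hif_stop("n_genes must be a positive count", "hif_config_error")
  if (!all(names(class_proportions) %in% GENE_CLASSES))
    hif_stop("class_proportions names outside the gene-class vocabulary", "hif_config_error")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    hif_stop("class_proportions must sum to 1", "hif_config_error")
  for (nm in c("n_sites_isoform1", "n_sites_isoform2", "n_sites_shared"))
    if (get(nm) < 0 || get(nm) != floor(get(nm)))
      hif_stop(paste0(nm, " must be a nonnegative count"), "hif_config_error")
  if (hif1b_coupling < 0 || hif1b_coupling > 1)
    hif_stop("hif1b_coupling must be in [0, 1]", "hif_config_error")
  if (censoring_rate < 0 || censoring_rate >= 1)
    hif_stop("censoring_rate must be in [0, 1)", "hif_config_error")
  if (n_patients < 3) hif_stop("n_patients must be >= 3", "hif_config_error")
  if (de_fraction < 0 || de_fraction > 1)
    hif_stop("de_fraction must be in [0, 1]", "hif_config_error")
  chrom_length <- chrom_length %||% (5000 * n_genes)
  if (n_genes > chrom_length)
    hif_stop("n_genes exceeds available positions on the virtual chromosome",
             "hif_config_error")
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 class_proportions = class_proportions,
                 n_sites_isoform1 = n_sites_isoform1,
                 n_sites_isoform2 = n_sites_isoform2,
                 n_sites_shared = n_sites_shared,
                 signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
                 hif1b_coupling = hif1b_coupling,
                 motif_base_rate = motif_base_rate, motif_slope = motif_slope,
                 n_patients = n_patients, latent_effect = latent_effect,
                 censoring_rate = censoring_rate, de_fraction = de_fraction,
                 de_lfc_scale = de_lfc_scale, chrom_length = chrom_length),
            class = "sim_config")
}

#' Simulate a gene annotation on a virtual chromosome
#'
#' Genes get distinct (hence non-overlapping) TSS positions on a single
#' virtual chromosome `chrS`, random strands, and class labels drawn from
#' the configured proportions.
#'
#' @param config A `sim_config`.
#' @return A `gene_annotation` data frame, sorted by TSS.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  tss <- sort(sample.int(config$chrom_length, config$n_genes))
  classes <- sample(names(config$class_proportions), config$n_genes,
                    replace = TRUE, prob = config$class_proportions)
  gene_annotation(id = sprintf("gene_%04d", seq_len(config$n_genes)),
                  chrom = "chrS", tss = tss,
                  strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
                  gene_class = classes)
}

## signal pair with an enforced >= `fold` gap on the pseudocounted ratio
rlnorm_gapped <- function(n, meanlog, sdlog, fold) {
  lo <- stats::rlnorm(n, meanlog, sdlog)
  gap <- exp(abs(rnorm(n, 0, 0.4)))
  hi <- fold * gap * (lo + 1) - 1
  list(hi = hi, lo = lo)
}

## log-scale coupling: rho = 1 gives an exactly proportional partner
couple_signal <- function(anchor, rho, sdlog) {
  la <- log(anchor + 1)
  lb <- rho * scale(la)[, 1] * sd(la) + mean(la) +
    sqrt(max(0, 1 - rho^2)) * rnorm(length(anchor), 0, sdlog)
  pmax(exp(lb) - 1, 0)
}

plant_motif <- function(sequence, motif, pos, strand) {
  if (strand == "-") motif <- reverse_complement(motif)
  paste0(substr(sequence, 1, pos - 1), motif,
         substr(sequence, pos + nchar(motif), nchar(sequence)))
}

#' Simulate binding sites, dual-caller peaks, signal and sequences
#'
#' Places isoform-1-specific, isoform-2-specific and shared sites near
#' distinct gene TSSs; draws log-normal signal with an enforced >= 3-fold
#' gap (on the pseudocounted ratio) for specific sites and a within-3-fold
#' ratio for shared sites; couples HIF-1beta signal to the dominant alpha
#' subunit at `hif1b_coupling`; emits two jittered caller interval sets
#' that both cover each true site; and generates summit +/- 150 bp
#' sequences with planted motif instances. The AP-1 consensus (TGACTCA)
#' is planted at isoform-2 sites with probability rising as the HIF-1beta
#' rank falls, and an HRE core (RCGTG) at all sites with probability
#' rising with HIF-1beta rank; with `motif_slope = 0` both plants are
#' rank- and class-independent at the base rate.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @return List with `sites` (`genomic_intervals`), `labels`
#'   (`isoform1_specific` / `isoform2_specific` / `shared`), `host_gene`,
#'   `caller_a`, `caller_b` (jittered interval sets), `signal`
#'   (`signal_matrix` over `H1A, H2A, H1B_ctrl, H1B_exp`), `sequences`
#'   (named character, width 301), `planted_ap1`, `planted_hre` (logical).
#' @export
simulate_binding <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "gene_annotation"))
  if (nrow(annotation) == 0) hif_stop("annotation is empty", "hif_config_error")
  set.seed(config$seed + 202L)
  n1 <- config$n_sites_isoform1; n2 <- config$n_sites_isoform2
  ns <- config$n_sites_shared
  n <- n1 + n2 + ns
  empty <- function() list(
    sites = genomic_intervals(character(), numeric(), numeric()),
    labels = character(), host_gene = character(),
    caller_a = genomic_intervals(character(), numeric(), numeric()),
    caller_b = genomic_intervals(character(), numeric(), numeric()),
    signal = NULL, sequences = character(),
    planted_ap1 = logical(), planted_hre = logical())
  if (n == 0) return(empty())
  if (n > nrow(annotation))
    hif_stop("more sites than genes to host them", "hif_config_error")
  labels <- rep(c("isoform1_specific", "isoform2_specific", "shared"),
                c(n1, n2, ns))
  host <- sample.int(nrow(annotation), n)
  centers <- pmax(annotation$tss[host] + round(runif(n, -5000, 5000)), 200)
  width <- 300L
  sites <- genomic_intervals("chrS", centers - width / 2, centers + width / 2,
                             summit = width / 2)

  ml <- config$signal_meanlog; sl <- config$signal_sdlog
  h1a <- h2a <- numeric(n)
  i1 <- labels == "isoform1_specific"; i2 <- labels == "isoform2_specific"
  sh <- labels == "shared"
  if (any(i1)) { g <- rlnorm_gapped(sum(i1), ml, sl, 3); h1a[i1] <- g$hi; h2a[i1] <- g$lo }
  if (any(i2)) { g <- rlnorm_gapped(sum(i2), ml, sl, 3); h2a[i2] <- g$hi; h1a[i2] <- g$lo }
  if (any(sh)) {
    base <- stats::rlnorm(sum(sh), ml, sl)
    ratio <- exp(runif(sum(sh), log(1 / 2.5), log(2.5)))
    h1a[sh] <- base; h2a[sh] <- base * ratio
  }
  # HIF-1beta follows whichever alpha subunit dominates each site
  alpha <- pmax(h1a, h2a)
  h1b_exp <- numeric(n)
  for (msk in list(i1, i2, sh)) if (any(msk))
    h1b_exp[msk] <- couple_signal(alpha[msk], config$hif1b_coupling, sl)
  h1b_ctrl <- couple_signal(h1b_exp, 0.9, sl / 2)
  signal <- signal_matrix(sites,
                          cbind(H1A = h1a, H2A = h2a,
                                H1B_ctrl = h1b_ctrl, H1B_exp = h1b_exp))

  jitter_set <- function() {
    ds <- round(runif(n, 0, 60)); de <- round(runif(n, 0, 60))
    genomic_intervals("chrS", pmax(sites$start - ds, 0), sites$end + de)
  }
  caller_a <- jitter_set(); caller_b <- jitter_set()

  seq_width <- 301L
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(BASES, seq_width, replace = TRUE), collapse = ""), "")
  # rank 1 = strongest HIF-1beta signal; frac -> 1 as the rank falls
  frac <- (rank(-h1b_exp, ties.method = "first") - 1) / max(1, n - 1)
  p_ap1 <- pmin(pmax(config$motif_base_rate +
                       config$motif_slope * frac * i2, 0), 1)
  p_hre <- pmin(pmax(config$motif_base_rate +
                       config$motif_slope * (1 - frac), 0), 1)
  if (config$motif_slope == 0) p_hre[] <- config$motif_base_rate
  planted_ap1 <- runif(n) < p_ap1
  planted_hre <- runif(n) < p_hre
  for (i in seq_len(n)) {
    if (planted_hre[i]) {
      # extended HRE consensus TRCGTGC: carries the RCGTG core but is long
      # enough that chance matches in uniform background stay rare
      core <- paste0("T", sample(c("A", "G"), 1), "CGTGC")
      seqs[i] <- plant_motif(seqs[i], core,
                             sample.int(seq_width - 6L, 1),
                             sample(c("+", "-"), 1))
    }
    if (planted_ap1[i]) {
      seqs[i] <- plant_motif(seqs[i], "TGACTCA",
                             sample.int(seq_width - 6L, 1),
                             sample(c("+", "-"), 1))
    }
  }
  names(seqs) <- sprintf("site_%04d", seq_len(n))
  list(sites = sites, labels = labels, host_gene = annotation$id[host],
       caller_a = caller_a, caller_b = caller_b, signal = signal,
       sequences = seqs, planted_ap1 = planted_ap1, planted_hre = planted_hre)
}

#' Simulate a two-condition RNA-seq count matrix
#'
#' Negative-binomial counts for 3 + 3 replicates with gene-specific
#' dispersion. Genes hosting isoform-1-specific sites receive positive
#' log2 fold-changes (emulating binding coupled to positive regulation);
#' additional unlinked genes are perturbed in either direction until the
#' configured DE fraction is met. `de_lfc_scale = 0` is a global null.
#'
#' @param config A `sim_config`.
#' @param annotation Output of [simulate_annotation()].
#' @param binding Output of [simulate_binding()] (may be `NULL` for a
#'   binding-free design).
#' @return List with `counts` (genes x 6), `groups` (factor `ctrl`/`exp`),
#'   `true_lfc`, `de_genes`.
#' @export
simulate_counts <- function(config, annotation, binding = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(annotation, "gene_annotation"))
  if (nrow(annotation) == 0) hif_stop("annotation is empty", "hif_config_error")
  set.seed(config$seed + 303L)
  ng <- nrow(annotation)
  mu <- stats::rlnorm(ng, log(200), 1.2)
  theta <- stats::rlnorm(ng, log(10), 0.3)
  lfc <- rep(0, ng)
  n_de <- round(config$de_fraction * ng)
  bound_up <- if (!is.null(binding))
    match(unique(binding$host_gene[binding$labels == "isoform1_specific"]),
          annotation$id)
  else integer(0)
  bound_up <- head(bound_up, n_de)
  lfc[bound_up] <- config$de_lfc_scale * runif(length(bound_up), 0.8, 2)
  extra <- setdiff(sample.int(ng), bound_up)[seq_len(max(0, n_de - length(bound_up)))]
  lfc[extra] <- config$de_lfc_scale * runif(length(extra), 0.8, 2) *
    sample(c(-1, 1), length(extra), replace = TRUE)
  groups <- factor(rep(c("ctrl", "exp"), each = 3), levels = c("ctrl", "exp"))
  counts <- matrix(0L, ng, 6,
                   dimnames = list(annotation$id, paste0(groups, "_", rep(1:3, 2))))
  for (j in 1:6) {
    m <- if (groups[j] == "exp") mu * 2^lfc else mu
    counts[, j] <- rnbinom(ng, size = theta, mu = m)
  }
  list(counts = counts, groups = groups, true_lfc = lfc,
       de_genes = annotation$id[lfc != 0])
}

#' Simulate a patient cohort driven by a latent prognostic factor
#'
#' Each patient carries a latent factor `z ~ N(0, 1)`. Listed genes get
#' expression `loading * z + noise` with random-sign loadings; survival is
#' exponential with hazard proportional to `exp(latent_effect * z)`,
#' censored by an independent exponential time calibrated to the
#' configured censoring fraction. Age, stage and metastasis are drawn so
#' the 0-4 prognostic score correlates with `z`; the deceased flag is the
#' observed-death indicator, as in a registry snapshot.
#'
#' @param config A `sim_config`.
#' @param genes Character vector of predictor gene ids (non-empty).
#' @return List with `expression` (patients x genes), `clinical`
#'   (data.frame `id, age, stage, metastasis, deceased, vital_status,
#'   time, event`), `latent` (z), `loadings`.
#' @export
simulate_cohort <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  if (!length(genes)) hif_stop("gene list is empty", "hif_config_error")
  set.seed(config$seed + 404L)
  n <- config$n_patients
  z <- rnorm(n)
  g <- length(genes)
  loadings <- setNames(sample(c(-1, 1), g, replace = TRUE) * runif(g, 0.5, 1), genes)
  expression <- outer(z, loadings) + matrix(rnorm(n * g), n, g)
  colnames(expression) <- genes
  lambda0 <- log(2) / 1000                      # baseline median ~1000 days
  t_event <- rexp(n, lambda0 * exp(config$latent_effect * z))
  cr <- config$censoring_rate
  t_cens <- if (cr > 0) rexp(n, lambda0 * cr / (1 - cr)) else rep(Inf, n)
  time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens
  age <- pmin(pmax(round(60 + 5 * z + rnorm(n, 0, 8)), 30), 90)
  stage <- as.integer(cut(z + rnorm(n, 0, 1),
                          breaks = c(-Inf, -0.6, 0.6, 1.4, Inf)))
  metastasis <- runif(n) < stats::plogis(z - 1.5)
  clinical <- data.frame(id = sprintf("pt_%04d", seq_len(n)),
                         age = age, stage = stage, metastasis = metastasis,
                         deceased = event,
                         vital_status = ifelse(event, "deceased", "alive"),
                         time = time, event = event, stringsAsFactors = FALSE)
  list(expression = expression, clinical = clinical, latent = z,
       loadings = loadings)
}

#' Write a full simulated dataset to disk
#'
#' Emits the caller BED files, peak-sequence FASTA, signal / count /
#' clinical TSVs and a manifest JSON, all through the package writers so
#' everything round-trips through the readers.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Named list of written paths (the manifest content), invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  bnd <- simulate_binding(config, ann)
  cnt <- simulate_counts(config, ann, bnd)
  coh <- simulate_cohort(config, unique(bnd$host_gene))
  p <- function(f) file.path(outdir, f)
  write_bed(bnd$caller_a, p("caller_a.bed"))
  write_bed(bnd$caller_b, p("caller_b.bed"))
  write_bed(bnd$sites, p("sites.bed"))
  write_fasta(bnd$sequences, p("sites.fa"))
  sig <- data.frame(region = names(bnd$sequences), bnd$signal$values,
                    check.names = FALSE)
  write.table(sig, p("signal.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = rownames(cnt$counts), cnt$counts,
                         check.names = FALSE),
              p("counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = ann$id, chrom = ann$chrom, tss = ann$tss,
                         strand = ann$strand, gene_class = ann$gene_class),
              p("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(coh$clinical, p("clinical.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(patient = coh$clinical$id, coh$expression,
                         check.names = FALSE),
              p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = config$seed,
                   files = c("caller_a.bed", "caller_b.bed", "sites.bed",
                             "sites.fa", "signal.tsv", "counts.tsv",
                             "genes.tsv", "clinical.tsv", "expression.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
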