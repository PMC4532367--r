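small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 5, n_genes = 300, n_sites_isoform1 = 40,
         n_sites_isoform2 = 40, n_sites_shared = 50, n_patients = 40),
    list(...))
  do.call(simulation_config, args)
}

test_that("simulation_config validates its fields", {
  expect_s3_class(small_cfg(), "sim_config")
  expect_error(simulation_config(class_proportions = c(protein_coding = 0.9)),
               class = "hif_config_error")
  expect_error(simulation_config(n_patients = 2), class = "hif_config_error")
  expect_error(simulation_config(censoring_rate = 1), class = "hif_config_error")
  expect_error(simulation_config(hif1b_coupling = 1.5), class = "hif_config_error")
  expect_error(simulation_config(n_genes = 100, chrom_length = 50),
               class = "hif_config_error")
})

test_that("simulate_annotation draws classes from the configured proportions", {
  cfg <- simulation_config(seed = 2, n_genes = 100,
                           class_proportions = c(protein_coding = 0.68,
                                                 other = 0.32))
  ann <- simulate_annotation(cfg)
  expect_s3_class(ann, "gene_annotation")
  expect_equal(nrow(ann), 100L)
  expect_true(all(ann$gene_class %in% c("protein_coding", "other")))
  frac <- mean(ann$gene_class == "protein_coding")
  expect_lt(abs(frac - 0.68), 3 * sqrt(0.68 * 0.32 / 100))
  expect_false(any(duplicated(ann$tss)))

  one <- simulate_annotation(simulation_config(seed = 3, n_genes = 1))
  expect_equal(nrow(one), 1L)
})

test_that("simulate_binding enforces the stated signal structure", {
  cfg <- small_cfg(hif1b_coupling = 1)
  ann <- simulate_annotation(cfg)
  bnd <- simulate_binding(cfg, ann)
  v <- bnd$signal$values
  i1 <- bnd$labels == "isoform1_specific"
  i2 <- bnd$labels == "isoform2_specific"
  sh <- bnd$labels == "shared"
  fold <- (v[, "H1A"] + 1) / (v[, "H2A"] + 1)
  expect_true(all(fold[i1] >= 3))
  expect_true(all(fold[i2] <= 1 / 3))
  expect_true(all(fold[sh] > 1 / 3 & fold[sh] < 3))

  # perfect coupling: HIF-1beta tracks the dominant subunit exactly
  expect_equal(cor(v[i1, "H1A"], v[i1, "H1B_exp"]), 1, tolerance = 1e-12)

  # classifier recovers the planted labels without error
  calls <- classify_isoform_specific(bnd$signal, "H1A", "H2A")
  expect_identical(calls$call, bnd$labels)

  # both callers cover every true site
  expect_true(all(bnd$caller_a$start <= bnd$sites$start &
                  bnd$caller_a$end >= bnd$sites$end))
  expect_equal(nchar(unname(bnd$sequences)), rep(301L, sum(cfg$n_sites_isoform1,
                  cfg$n_sites_isoform2, cfg$n_sites_shared)))

  empty <- simulate_binding(small_cfg(n_sites_isoform1 = 0,
                                      n_sites_isoform2 = 0,
                                      n_sites_shared = 0), ann)
  expect_equal(nrow(empty$sites), 0L)
})

test_that("simulate_counts couples positive fold changes to isoform-1 binding", {
  cfg <- small_cfg()
  ann <- simulate_annotation(cfg)
  bnd <- simulate_binding(cfg, ann)
  cnt <- simulate_counts(cfg, ann, bnd)
  expect_equal(dim(cnt$counts), c(300L, 6L))
  expect_equal(levels(cnt$groups), c("ctrl", "exp"))
  host1 <- unique(bnd$host_gene[bnd$labels == "isoform1_specific"])
  planted <- cnt$true_lfc[match(host1, rownames(cnt$counts))]
  expect_true(all(planted[planted != 0] > 0))
  expect_equal(sum(cnt$true_lfc != 0), round(cfg$de_fraction * cfg$n_genes))

  null_cfg <- small_cfg(de_lfc_scale = 0)
  cnt0 <- simulate_counts(null_cfg, ann, bnd)
  expect_true(all(cnt0$true_lfc == 0))
})

test_that("simulate_cohort builds a latent-factor cohort with valid clinical data", {
  cfg <- small_cfg(censoring_rate = 0)
  coh <- simulate_cohort(cfg, sprintf("g%02d", 1:12))
  expect_true(all(coh$clinical$event))     # no censoring: every death observed
  expect_true(all(coh$clinical$time > 0))
  expect_true(all(coh$clinical$stage %in% 1:4))
  expect_identical(coh$clinical$deceased, coh$clinical$event)

  # expression aligns with loadings: correlation with z matches loading sign
  cors <- cor(coh$expression, coh$latent)[, 1]
  expect_true(all(sign(cors) == sign(coh$loadings)))

  # prognostic score correlates with the latent factor
  sc <- prognostic_score(coh$clinical)
  expect_gt(cor(sc$score, coh$latent), 0.3)

  expect_error(simulate_cohort(cfg, character()), class = "hif_config_error")
})

test_that("identical seed and config give identical outputs", {
  cfg <- small_cfg()
  ann1 <- simulate_annotation(cfg); ann2 <- simulate_annotation(cfg)
  expect_identical(ann1, ann2)
  b1 <- simulate_binding(cfg, ann1); b2 <- simulate_binding(cfg, ann2)
  expect_identical(b1, b2)
  expect_identical(simulate_counts(cfg, ann1, b1), simulate_counts(cfg, ann2, b2))
  expect_identical(simulate_cohort(cfg, b1$host_gene[1:10]),
                   simulate_cohort(cfg, b2$host_gene[1:10]))
})

test_that("emitted files parse back through the readers", {
  cfg <- small_cfg()
  outdir <- withr::local_tempdir()
  manifest <- write_simulation(cfg, outdir)
  expect_true(all(file.exists(file.path(outdir, manifest$files))))

  a <- read_bed(file.path(outdir, "caller_a.bed"))
  expect_s3_class(a, "genomic_intervals")
  expect_equal(nrow(a), 130L)

  seqs <- read_fasta(file.path(outdir, "sites.fa"))
  expect_length(seqs, 130L)

  sig <- read_table(file.path(outdir, "signal.tsv"),
                    c(region = "character", H1A = "numeric", H2A = "numeric",
                      H1B_ctrl = "numeric", H1B_exp = "numeric"))
  expect_equal(nrow(sig), 130L)

  cl <- read_clinical(file.path(outdir, "clinical.tsv"))
  expect_equal(nrow(cl), cfg$n_patients)
})
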