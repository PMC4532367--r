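test_that("compute_rpkm matches its unit definition and is bilinear", {
  expect_equal(compute_rpkm(100, 1000, 1e6), 100)
  expect_equal(compute_rpkm(0, 1000, 1e6), 0)
  expect_equal(compute_rpkm(50, 500, 2e6), 50)
  expect_error(compute_rpkm(10, 0, 1e6), class = "hif_domain_error")
  expect_error(compute_rpkm(10, 100, 0), class = "hif_domain_error")

  set.seed(42)
  for (i in 1:20) {
    cnt <- runif(1, 0, 1e4); len <- runif(1, 100, 1e5); lib <- runif(1, 1e5, 1e8)
    a <- runif(1, 0.1, 10)
    expect_equal(compute_rpkm(a * cnt, len, lib), a * compute_rpkm(cnt, len, lib))
    expect_equal(compute_rpkm(cnt, len, a * lib), compute_rpkm(cnt, len, lib) / a)
  }
})

test_that("consensus_peaks keeps only reciprocally supported base pairs", {
  A <- genomic_intervals("chr1", 100, 300)
  B <- genomic_intervals("chr1", 200, 400)
  cons <- consensus_peaks(A, B)
  expect_equal(cons$start, 200)
  expect_equal(cons$end, 300)

  expect_equal(nrow(consensus_peaks(genomic_intervals("chr1", 100, 200),
                                    genomic_intervals("chr1", 300, 400))), 0L)

  A2 <- genomic_intervals("chr1", c(0, 150), c(100, 250))
  B2 <- genomic_intervals("chr1", 50, 300)
  c2 <- consensus_peaks(A2, B2)
  expect_equal(c2$start, c(50, 150))
  expect_equal(c2$end, c(100, 250))
})

test_that("consensus_peaks equals brute-force bp intersection on random cases", {
  set.seed(7)
  for (rep in 1:15) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    mk <- function(n) {
      s <- sample(0:2000, n)
      genomic_intervals("chrT", s, s + sample(20:400, n, replace = TRUE))
    }
    a <- mk(na); b <- mk(nb)
    got <- consensus_peaks(a, b)
    want <- brute_consensus(a, b)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("background_threshold uses the nearest-rank upper quantile", {
  expect_equal(background_threshold(sample(1:10000), 1e-4), 10000)
  expect_equal(background_threshold(rep(3.5, 200), 0.01), 3.5)
  expect_warning(background_threshold(1:100, 1e-4), "coarse")
  expect_error(background_threshold(numeric(0), 1e-4), class = "hif_domain_error")
  expect_error(background_threshold(1:10, 0), class = "hif_domain_error")
  # exactly floor(n * p) background values sit at or above the threshold
  set.seed(11)
  v <- rnorm(5000)
  thr <- background_threshold(v, 0.01)
  expect_equal(sum(v >= thr), 50L)
})

test_that("filter_peaks applies an inclusive threshold", {
  pk <- genomic_intervals("chr1", c(0, 100, 200), c(50, 150, 250))
  suppressMessages({
    res <- filter_peaks(pk, c(5, 50, 500), 50)
    expect_equal(sum(res$kept), 2L)
    expect_equal(nrow(filter_peaks(pk, c(5, 50, 500), 0)$peaks), 3L)
    expect_equal(nrow(filter_peaks(pk, c(5, 50, 500), 1000)$peaks), 0L)
  })
  expect_error(filter_peaks(pk, c(1, 2), 0), class = "hif_validation_error")
})

test_that("signal_scatter summarizes equity and correlation", {
  set.seed(3)
  x <- rlnorm(400, 3, 1)
  iv <- genomic_intervals("chr1", seq_len(400) * 1000, seq_len(400) * 1000 + 300)
  m <- signal_matrix(iv, cbind(a = x, b = x, c = 2 * x))
  same <- signal_scatter(m, "a", "b")
  expect_equal(same$pearson, 1)
  expect_equal(same$fraction_above, 0)   # ties count below the line
  dbl <- signal_scatter(m, "a", "c")
  expect_equal(dbl$fraction_above, 1)
  expect_gt(dbl$pearson, 0.99)

  tiny <- signal_matrix(iv[1:2, ], cbind(a = x[1:2], b = x[1:2]))
  expect_match(signal_scatter(tiny, "a", "b")$flag, "fewer than 3")

  ind <- signal_matrix(iv, cbind(a = rlnorm(400, 3, 1), b = rlnorm(400, 3, 1)))
  expect_lt(abs(signal_scatter(ind, "a", "b")$pearson), 0.15)
})

test_that("pca_biplot decomposes the centered log signal", {
  set.seed(9)
  n <- 300
  base <- rlnorm(n, 3, 1)
  iv <- genomic_intervals("chr1", seq_len(n) * 1000, seq_len(n) * 1000 + 300)
  m <- signal_matrix(iv, cbind(c1 = base, c2 = base * rlnorm(n, 0, 0.05),
                               c3 = rlnorm(n, 3, 1)))
  bp <- pca_biplot(m)
  expect_equal(dim(bp$site_scores), c(n, 2L))
  expect_equal(dim(bp$condition_loadings), c(3L, 2L))
  expect_true(all(diff(bp$explained_variance) <= 1e-12))
  expect_true(all(bp$explained_variance >= 0 & bp$explained_variance <= 1))
  expect_lte(sum(bp$explained_variance), 1 + 1e-12)

  # identical conditions load in parallel on the one informative component
  m2 <- signal_matrix(iv, cbind(c1 = base, c2 = base))
  bp2 <- pca_biplot(m2)
  expect_equal(bp2$condition_loadings[1, 1], bp2$condition_loadings[2, 1],
               tolerance = 1e-10)
  expect_equal(bp2$explained_variance[1], 1, tolerance = 1e-10)

  # full reconstruction when all components are kept
  full <- pca_biplot(m, n_components = NULL)
  vc <- sweep(log2(m$values + 1), 2, full$center)
  expect_lt(max(abs(full$site_scores %*% t(full$condition_loadings) - vc)), 1e-8)

  # sign convention: dominant loading of each component is positive
  expect_true(all(apply(full$condition_loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))

  # independent conditions give near-orthogonal loadings
  m3 <- signal_matrix(iv, cbind(c1 = rlnorm(n, 3, 1), c2 = rlnorm(n, 3, 1)))
  l3 <- pca_biplot(m3)$condition_loadings
  expect_lt(abs(sum(l3[1, ] * l3[2, ])), 0.2)

  const <- signal_matrix(iv, cbind(c1 = rep(2, n), c2 = rep(5, n)))
  expect_true(pca_biplot(const)$degenerate)
})
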