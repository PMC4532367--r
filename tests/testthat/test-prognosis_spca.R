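test_that("prognostic_score adds the four clinical indicators", {
  cl <- data.frame(age = c(55, 65, 61, 70), stage = c(2, 3, 1, 4),
                   metastasis = c(FALSE, TRUE, FALSE, NA),
                   deceased = c(FALSE, TRUE, FALSE, TRUE))
  suppressMessages(sc <- prognostic_score(cl))
  expect_equal(sc$score, c(0L, 4L, 1L))       # row 4 excluded: missing field
  expect_equal(sc$group, c("good", "poor", "good"))
  expect_equal(attr(sc, "excluded"), 4L)
  expect_error(prognostic_score(data.frame(age = 1)), class = "hif_schema_error")
})

test_that("km_estimator reproduces hand-computed product-limit curves", {
  fit <- km_estimator(c(1, 2), c(TRUE, TRUE))
  expect_equal(fit$time, c(1, 2))
  expect_equal(fit$surv, c(0.5, 0))
  expect_equal(km_surv_at(fit, c(0.5, 1.5, 3)), c(1, 0.5, 0))

  none <- km_estimator(c(4, 6, 8), c(FALSE, FALSE, FALSE))
  expect_equal(km_surv_at(none, 10), 1)

  cens <- km_estimator(c(2, 5, 5), c(TRUE, FALSE, FALSE))
  expect_equal(km_surv_at(cens, c(1, 3)), c(1, 2/3))

  expect_error(km_estimator(numeric(0), logical(0)), class = "hif_domain_error")
})

test_that("km_estimator agrees with survival::survfit on random fixtures", {
  set.seed(53)
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    tm <- sample(1:8, n, replace = TRUE)
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    ours <- km_estimator(tm, ev)
    ref <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    at <- sort(unique(tm))
    expect_equal(km_surv_at(ours, at),
                 summary(ref, times = at)$surv, tolerance = 1e-12)
  }
})

test_that("cox_fit returns Wald inference and degrades gracefully", {
  set.seed(59)
  n <- 150
  z <- rnorm(n)
  tm <- rexp(n, 0.01 * exp(z)); ev <- runif(n) < 0.8
  fit <- cox_fit(z, tm, ev)
  expect_null(fit$flag)
  expect_gt(fit$hazard_ratio, 1)
  expect_true(fit$ci95[1] <= fit$hazard_ratio && fit$hazard_ratio <= fit$ci95[2])
  expect_lt(fit$pvalue, 0.01)

  one_event <- cox_fit(z[1:5], tm[1:5], c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(one_event$flag, "fewer than 2 events")
  expect_error(cox_fit(rep(1, 10), tm[1:10], ev[1:10]), class = "hif_domain_error")
})

test_that("cox_fit direction agrees with the logrank statistic on binary covariates", {
  set.seed(61)
  for (rep in 1:50) {
    n <- 60
    g <- rep(0:1, each = n / 2)
    tm <- rexp(n, 0.01 * exp(runif(1, -1, 1) * g))
    ev <- rep(TRUE, n)
    fit <- cox_fit(g, tm, ev)
    sd1 <- survival::survdiff(survival::Surv(tm, ev) ~ g)
    # observed > expected deaths in group 1 <=> positive log hazard ratio
    expect_equal(sign(fit$coef), sign(sd1$obs[2] - sd1$exp[2]))
  }
})

test_that("the vectorized screen matches per-gene coxph fits", {
  co <- small_cohort(n = 100, n_genes = 8)
  Z <- scale(co$x)
  fast <- hifbind:::cox_univariate_fast(Z, co$time, co$event)
  for (j in seq_len(ncol(Z))) {
    ref <- survival::coxph(survival::Surv(co$time, co$event) ~ Z[, j])
    expect_equal(fast$coef[j], unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fast$pvalue[j],
                 summary(ref)$coefficients[1, "Pr(>|z|)"], tolerance = 1e-6)
  }
})

test_that("univariate_screen keeps strongly prognostic genes and honors alpha", {
  co <- small_cohort(n = 400, n_genes = 10, effect = 1.2, seed = 67)
  genes <- univariate_screen(co$x, co$time, co$event, alpha = 0.05)
  expect_setequal(genes, colnames(co$x))   # all genes load on the latent factor

  suppressMessages(
    none <- univariate_screen(co$x, co$time, co$event, alpha = 0))
  expect_length(none, 0)
})

test_that("spca_fit yields unit-norm hazard-oriented weights", {
  co <- small_cohort(n = 200, n_genes = 6, effect = 1, seed = 71)
  model <- spca_fit(co$x, co$time, co$event)
  expect_equal(sum(model$weights^2), 1)
  expect_equal(predict_risk(model, co$x), model$scores)
  # orientation: higher score, higher hazard
  expect_gt(cox_fit(model$scores, co$time, co$event)$coef, 0)
  # weight signs follow the planted loadings
  expect_true(mean(sign(model$weights) == sign(co$loadings)) >= 5 / 6 ||
              mean(sign(model$weights) == -sign(co$loadings)) >= 5 / 6)

  # two identical genes split the weight evenly
  x2 <- cbind(g1 = co$x[, 1], g2 = co$x[, 1])
  m2 <- spca_fit(x2, co$time, co$event)
  expect_equal(abs(unname(m2$weights)), rep(1 / sqrt(2), 2))

  expect_error(spca_fit(co$x[, 1, drop = FALSE], co$time, co$event),
               class = "hif_domain_error")
})

test_that("spca_fit is invariant to patient and gene reordering", {
  co <- small_cohort(n = 150, n_genes = 7, seed = 73)
  m <- spca_fit(co$x, co$time, co$event)
  pp <- sample(nrow(co$x)); gp <- sample(ncol(co$x))
  m2 <- spca_fit(co$x[pp, gp], co$time[pp], co$event[pp])
  expect_equal(m2$weights[colnames(co$x)], m$weights, tolerance = 1e-9)
  expect_equal(m2$scores, m$scores[pp], tolerance = 1e-9)
})

test_that("loo_cv refits the fold pipeline and handles degenerate cohorts", {
  co <- small_cohort(n = 40, n_genes = 6, effect = 1.5, seed = 79)
  cv <- loo_cv(co$x, co$time, co$event)
  expect_equal(cv$fold_size, 39L)
  expect_length(cv$scores, 40)

  # duplicated patients: every fold sees the same data, scores agree across copies
  dup_idx <- rep(1:10, 4)
  co10 <- list(x = co$x[dup_idx, ], time = co$time[dup_idx], event = co$event[dup_idx])
  cv_dup <- loo_cv(co10$x, co10$time, co10$event)
  by_patient <- split(cv_dup$scores, dup_idx)
  expect_true(all(vapply(by_patient, function(s) diff(range(s)) < 1e-8, TRUE)))

  expect_error(loo_cv(co$x[1:5, ], co$time[1:5], co$event[1:5]),
               class = "hif_domain_error")
})

test_that("median_split_eval stratifies risk groups", {
  co <- small_cohort(n = 200, n_genes = 8, effect = 1.5, seed = 83)
  model <- spca_fit(co$x, co$time, co$event)
  ev <- median_split_eval(model$scores, co$time, co$event)
  expect_gt(ev$fit$hazard_ratio, 1)
  expect_lt(ev$fit$pvalue, 0.01)
  expect_equal(sum(ev$group), 100L)
  expect_true(all(km_surv_at(ev$km_high, 500) <= km_surv_at(ev$km_low, 500)))

  expect_error(median_split_eval(rep(1, 10), co$time[1:10], co$event[1:10]),
               class = "hif_domain_error")
  tiny <- median_split_eval(c(1, 2, 3, 4), c(5, 6, 7, 8), c(TRUE, TRUE, TRUE, FALSE))
  expect_true(is.list(tiny$fit))
})
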