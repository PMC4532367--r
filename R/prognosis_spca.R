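## Clinical prognostic stratification, Kaplan-Meier / Cox machinery, and
## the supervised principal components (SPCA) gene predictor with
## leave-one-out cross-validation.

#' Clinical prognostic score (0-4) and good/poor group
#'
#' Adds 1 for each of: age over 60, pathologic stage 3 or 4, presence of
#' metastasis, patient deceased. Scores 0-1 are "good" prognosis, 2-4
#' "poor". Note the deceased indicator overlaps the survival outcome:
#' this stratification is meant for expression contrasts, not as a
#' covariate in survival models evaluated on the same patients.
#'
#' @param clinical data.frame with columns `age`, `stage`, `metastasis`,
#'   `deceased`. Rows with any of the four missing are excluded (logged).
#' @return data.frame with `score` (integer 0-4) and `group`
#'   (`"good"`/`"poor"`) for the retained rows; attribute `excluded` holds
#'   the dropped row indices.
#' @export
prognostic_score <- function(clinical) {
  need <- c("age", "stage", "metastasis", "deceased")
  if (!all(need %in% names(clinical)))
    hif_stop(paste0("missing clinical field(s): ",
                    paste(setdiff(need, names(clinical)), collapse = ", ")),
             "hif_schema_error")
  ok <- complete.cases(clinical[need])
  if (any(!ok)) hif_log("prognostic_score: excluded %d patient(s) with missing fields", sum(!ok))
  cl <- clinical[ok, , drop = FALSE]
  score <- (cl$age > 60) + (cl$stage >= 3) + cl$metastasis + cl$deceased
  out <- data.frame(score = as.integer(score),
                    group = ifelse(score <= 1, "good", "poor"),
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(cl))) rownames(out) <- rownames(cl)
  attr(out, "excluded") <- which(!ok)
  out
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times Follow-up times (> 0).
#' @param events Logical event indicators (TRUE = death observed).
#' @return List with `time` (distinct event times), `surv` (S(t) just
#'   after each event time), `n_risk`, `n_event`. `S(0) = 1`; the curve is
#'   right-continuous.
#' @export
km_estimator <- function(times, events) {
  if (!length(times)) hif_stop("need >= 1 subject", "hif_domain_error")
  events <- as.logical(events)
  et <- sort(unique(times[events]))
  n_risk <- vapply(et, function(t) sum(times >= t), 0)
  n_event <- vapply(et, function(t) sum(times == t & events), 0)
  surv <- cumprod(1 - n_event / n_risk)
  list(time = et, surv = surv, n_risk = n_risk, n_event = n_event)
}

#' Evaluate a Kaplan-Meier curve at given times
#' @param km Output of [km_estimator()].
#' @param t Times at which to evaluate S(t).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    i <- sum(km$time <= tt)
    if (i == 0) 1 else km$surv[i]
  }, 0)
}

#' Univariate Cox proportional-hazards fit
#'
#' Wraps [survival::coxph()] with the Efron tie approximation and returns
#' the Wald-based summary. Degenerate inputs (< 2 events) return a flagged
#' result rather than crashing; a constant covariate is an error.
#'
#' @param covariate Numeric (or two-level) covariate, one value per patient.
#' @param times Follow-up times.
#' @param events Logical event indicators.
#' @return List with `coef`, `hazard_ratio`, `ci95` (HR scale), `pvalue`,
#'   `n_event`, `flag` (NULL when clean).
#' @export
cox_fit <- function(covariate, times, events) {
  events <- as.logical(events)
  if (length(unique(covariate)) == 1L)
    hif_stop("constant covariate", "hif_domain_error")
  if (sum(events) < 2) {
    return(list(coef = NA_real_, hazard_ratio = NA_real_,
                ci95 = c(NA_real_, NA_real_), pvalue = NA_real_,
                n_event = sum(events), flag = "fewer than 2 events"))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(times, events) ~ covariate, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(survival::Surv(times, events) ~ covariate,
                                       ties = "efron"))
    })
  if (is.null(fit) || !is.finite(coef(fit)[1])) {
    return(list(coef = NA_real_, hazard_ratio = NA_real_,
                ci95 = c(NA_real_, NA_real_), pvalue = NA_real_,
                n_event = sum(events), flag = "non-convergence"))
  }
  s <- summary(fit)
  b <- unname(coef(fit)[1]); se <- s$coefficients[1, "se(coef)"]
  list(coef = b, hazard_ratio = exp(b),
       ci95 = exp(b + c(-1, 1) * qnorm(0.975) * se),
       pvalue = unname(s$coefficients[1, "Pr(>|z|)"]),
       n_event = sum(events), flag = NULL)
}

#' Univariate Cox screen over a gene expression matrix
#'
#' Each gene is standardized (mean 0, SD 1) and tested one at a time in a
#' univariate Cox model; genes with Wald p < `alpha` pass. Untied event
#' times are fitted by an internal vectorized Newton solver (identical to
#' `coxph` in that case); tied data fall back to [cox_fit()] per gene.
#'
#' @param expression Patients x genes numeric matrix (named columns).
#' @param times,events Survival data aligned with rows.
#' @param alpha Screening level, default 0.05.
#' @param beta_init Optional per-gene starting coefficients for the Newton
#'   solver (a warm start; does not change the optimum).
#' @return Character vector of passing gene names (possibly empty, logged),
#'   with the per-gene p-values as attribute `pvalues`.
#' @export
univariate_screen <- function(expression, times, events, alpha = 0.05,
                              beta_init = NULL) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2) hif_stop("need >= 2 genes to screen", "hif_domain_error")
  sds <- col_sds(expression)
  keep <- sds > 0
  Z <- sweep(sweep(expression[, keep, drop = FALSE], 2L,
                   colMeans(expression[, keep, drop = FALSE])),
             2L, sds[keep], "/")
  if (!is.null(beta_init) && !is.null(names(beta_init)))
    beta_init <- unname(beta_init[colnames(Z)])
  ties_present <- anyDuplicated(times[as.logical(events)]) > 0
  if (!ties_present) {
    res <- cox_univariate_fast(Z, times, events, beta_init = beta_init)
    pv <- setNames(res$pvalue, colnames(Z))
  } else {
    pv <- vapply(colnames(Z), function(g) {
      cox_fit(Z[, g], times, events)$pvalue
    }, 0)
  }
  pass <- names(pv)[!is.na(pv) & pv < alpha]
  if (!length(pass)) hif_log("univariate_screen: no gene passed at alpha=%g", alpha)
  attr(pass, "pvalues") <- pv
  pass
}

#' Supervised principal components fit
#'
#' Centers and scales each screened gene, takes the SVD of the patients x
#' genes matrix, and uses the first right singular vector as gene weights
#' (unit norm). Each patient's risk score is the projection onto the
#' weights; the sign is oriented so that a higher score means higher
#' hazard (checked with a Cox fit of the score on the training data).
#'
#' @param expression Patients x screened-genes matrix (>= 2 genes,
#'   >= 3 patients).
#' @param times,events Survival data aligned with rows.
#' @return List of class `predictor_model` with `genes`, `weights`
#'   (unit norm), `centering`, `scale`, and `scores` (training risk
#'   scores).
#' @export
spca_fit <- function(expression, times, events) {
  expression <- as.matrix(expression)
  if (ncol(expression) < 2)
    hif_stop("screen produced < 2 genes; relax alpha", "hif_domain_error")
  if (nrow(expression) < 3) hif_stop("need >= 3 patients", "hif_domain_error")
  ctr <- colMeans(expression)
  scl <- col_sds(expression)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(expression, 2L, ctr), 2L, scl, "/")
  sv <- svd(Z, nu = 0, nv = 1)
  w <- sv$v[, 1]
  scores <- as.numeric(Z %*% w)
  # orient: higher score -> higher hazard
  cf <- cox_univariate_fast(matrix(scores, ncol = 1), times, as.logical(events))
  if (is.finite(cf$coef[1]) && cf$coef[1] < 0) { w <- -w; scores <- -scores }
  structure(list(genes = colnames(expression), weights = setNames(w, colnames(expression)),
                 centering = ctr, scale = scl, scores = scores),
            class = "predictor_model")
}

#' Project new patients onto a fitted predictor
#' @param model A `predictor_model`.
#' @param expression Patients x genes matrix containing the model's genes.
#' @return Numeric risk scores.
#' @export
predict_risk <- function(model, expression) {
  expression <- as.matrix(expression)[, model$genes, drop = FALSE]
  Z <- sweep(sweep(expression, 2L, model$centering), 2L, model$scale, "/")
  as.numeric(Z %*% model$weights)
}

#' Leave-one-out cross-validated SPCA risk scores
#'
#' For each patient, the univariate screen and the SPCA fit are redone on
#' the remaining n - 1 patients and the held-out patient is projected with
#' that fold's centering, scale and weights. Folds where the screen
#' returns fewer than 2 genes yield `NA` (logged). The procedure is
#' deterministic (no randomness).
#'
#' @param expression Patients x candidate-genes matrix.
#' @param times,events Survival data aligned with rows.
#' @param alpha Screening level per fold, default 0.05.
#' @return List with `scores` (out-of-fold risk per patient), `n_genes`
#'   (screened genes per fold), `fold_size` (training patients per fold).
#' @export
loo_cv <- function(expression, times, events, alpha = 0.05) {
  expression <- as.matrix(expression)
  n <- nrow(expression)
  if (n < 10) hif_stop("need >= 10 patients for LOO-CV", "hif_domain_error")
  scores <- rep(NA_real_, n)
  n_genes <- integer(n)
  # warm-start each fold's Newton solver at the full-data coefficients;
  # this speeds convergence without changing any fold's optimum
  sds <- col_sds(expression)
  full <- cox_univariate_fast(scale(expression[, sds > 0, drop = FALSE]),
                              times, as.logical(events))
  warm <- setNames(rep(0, ncol(expression)), colnames(expression))
  warm[rownames(full)] <- full$coef
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    genes <- univariate_screen(expression[tr, , drop = FALSE],
                               times[tr], events[tr], alpha,
                               beta_init = warm)
    n_genes[i] <- length(genes)
    if (length(genes) < 2) next
    model <- spca_fit(expression[tr, genes, drop = FALSE], times[tr], events[tr])
    scores[i] <- predict_risk(model, expression[i, , drop = FALSE])
  }
  if (anyNA(scores))
    hif_log("loo_cv: %d fold(s) failed the screen; scores set NA", sum(is.na(scores)))
  list(scores = scores, n_genes = n_genes, fold_size = n - 1L)
}

#' Median-split survival evaluation of risk scores
#'
#' Splits patients at the median risk score (ties go to the low group),
#' fits a Cox model on the binary group indicator, and returns
#' Kaplan-Meier curves per group.
#'
#' @param scores Per-patient risk scores (NA scores dropped, logged).
#' @param times,events Survival data aligned with `scores`.
#' @return List with `fit` (from [cox_fit()] on the high-vs-low
#'   indicator), `km_high`, `km_low`, `group` (logical, high risk).
#' @export
median_split_eval <- function(scores, times, events) {
  ok <- !is.na(scores)
  if (any(!ok)) hif_log("median_split_eval: dropped %d NA score(s)", sum(!ok))
  scores <- scores[ok]; times <- times[ok]; events <- as.logical(events)[ok]
  high <- scores > median(scores)
  if (all(high) || !any(high)) hif_stop("degenerate split: all scores tied", "hif_domain_error")
  if (sum(high) < 2 || sum(!high) < 2)
    hif_stop("need >= 2 patients per group", "hif_domain_error")
  fit <- cox_fit(as.numeric(high), times, events)
  list(fit = fit, km_high = km_estimator(times[high], events[high]),
       km_low = km_estimator(times[!high], events[!high]), group = high)
}
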