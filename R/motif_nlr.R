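## Normalized likelihood-ratio PWM scanning and the motif-trend /
## differential-distribution analyses built on it.
##
## The scanner's per-window statistic is the arithmetic mean over motif
## positions of the probability ratio PWM(b, i) / B(b) — the "mean" form —
## rather than the conventional product of ratios. Both forms are exposed
## via `form`; the mean form is the default and is what the trend and
## differential analyses are calibrated on. See the methods vignette.

BASES <- c("A", "C", "G", "T")

#' Convert a count matrix to a position weight matrix
#'
#' `probs[b, i] = (counts[b, i] + pseudocount) / (colsum_i + 4 * pseudocount)`.
#' The default pseudocount of 0.25 per cell keeps every entry positive
#' while perturbing the observed frequencies minimally.
#'
#' @param counts Nonnegative 4 x L matrix, rows A, C, G, T.
#' @param pseudocount Added to every cell before normalization.
#' @return A `pwm` object: 4 x L probability matrix, columns summing to 1.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) hif_stop("counts must have 4 base rows", "hif_validation_error")
  if (any(counts < 0)) hif_stop("negative counts", "hif_validation_error")
  cs <- colSums(counts) + 4 * pseudocount
  if (any(cs == 0))
    hif_stop("all-zero column with pseudocount = 0", "hif_domain_error")
  probs <- sweep(counts + pseudocount, 2L, cs, "/")
  rownames(probs) <- BASES
  structure(probs, class = "pwm", motif_id = attr(counts, "motif_id"))
}

#' Background base frequencies from a set of sequences
#'
#' Pools all sequences, drops N/ambiguous bases, and adds one pseudocount
#' per base so that no base has weight zero even in skewed backgrounds.
#'
#' @param sequences Character vector of DNA sequences.
#' @return Named numeric vector (A, C, G, T) summing to 1.
#' @export
background_from_regions <- function(sequences) {
  chars <- strsplit(toupper(paste(sequences, collapse = "")), "")[[1]]
  counts <- table(factor(chars[chars %in% BASES], levels = BASES))
  if (sum(counts) == 0) hif_stop("no informative (ACGT) bases", "hif_domain_error")
  freqs <- (as.numeric(counts) + 1) / (sum(counts) + 4)
  setNames(freqs, BASES)
}

## map sequence to integer codes 1..4 (A,C,G,T), NA for anything else
seq_to_codes <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], BASES)
}

#' Normalized likelihood-ratio profile of a sequence
#'
#' For each window position j in `0 .. W - L`, computes the normalized
#' likelihood ratio of the window against the background model. With
#' `form = "mean"` (default) this is the arithmetic mean over motif
#' positions i of `PWM(b, i) / B(b)` for the base b at `j + i`; with
#' `form = "product"` it is the geometric mean of those ratios (the
#' conventional per-position-normalized likelihood ratio). Windows that
#' contain any non-ACGT base get NLR = 0 and are flagged.
#'
#' @param sequence DNA sequence of width W >= L.
#' @param pwm A `pwm` object (4 x L).
#' @param background Named background weights from
#'   [background_from_regions()].
#' @param form `"mean"` or `"product"`.
#' @return Numeric vector of length `W - L + 1` with attribute
#'   `masked` (logical, windows containing N).
#' @export
nlr_profile <- function(sequence, pwm, background, form = c("mean", "product")) {
  form <- match.arg(form)
  L <- ncol(pwm)
  codes <- seq_to_codes(sequence)
  W <- length(codes)
  if (W < L) hif_stop("sequence shorter than motif", "hif_domain_error")
  ratio <- pwm / background[BASES]          # 4 x L ratio matrix
  if (form == "product") ratio <- log(ratio)
  nw <- W - L + 1L
  # windows x L index matrix into the sequence
  idx <- outer(seq_len(nw), 0:(L - 1L), `+`)
  b <- codes[idx]                            # windows x L base codes (NA for N)
  masked <- rowSums(is.na(matrix(b, nrow = nw))) > 0
  r <- matrix(ratio[cbind(as.vector(b), rep(seq_len(L), each = nw))], nrow = nw)
  vals <- rowMeans(r)
  if (form == "product") vals <- exp(vals)
  vals[masked] <- 0
  attr(vals, "masked") <- masked
  vals
}

reverse_complement <- function(sequence) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", sequence), "")[[1]]),
        collapse = "")
}

#' Peak normalized likelihood ratio (maximum over windows)
#'
#' Scans a region for the motif and reports the maximum NLR over all
#' window positions, optionally across both strands (the reverse strand is
#' scanned on the reverse complement). Ties are broken by the smallest
#' offset, then by the forward strand.
#'
#' @inheritParams nlr_profile
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return List with `pnlr`, `log_pnlr` (`log2(pnlr)`), `best_offset`
#'   (0-based, in the scanned strand's coordinates) and `best_strand`.
#' @export
pnlr <- function(sequence, pwm, background, both_strands = TRUE,
                 form = c("mean", "product")) {
  form <- match.arg(form)
  fwd <- nlr_profile(sequence, pwm, background, form)
  best <- c(max(fwd), which.max(fwd) - 1L, 1L)   # value, offset, strand code
  if (both_strands) {
    rev <- nlr_profile(reverse_complement(sequence), pwm, background, form)
    if (max(rev) > best[1]) best <- c(max(rev), which.max(rev) - 1L, 2L)
  }
  list(pnlr = best[1], log_pnlr = log2(best[1]),
       best_offset = as.integer(best[2]),
       best_strand = c("+", "-")[best[3]])
}

#' Scan many regions for a motif
#'
#' @param sequences Named character vector of region sequences.
#' @inheritParams pnlr
#' @return data.frame with one row per region: `region`, `pnlr`,
#'   `log_pnlr`, `best_offset`, `best_strand`.
#' @export
scan_regions <- function(sequences, pwm, background, both_strands = TRUE,
                         form = c("mean", "product")) {
  form <- match.arg(form)
  res <- lapply(sequences, pnlr, pwm = pwm, background = background,
                both_strands = both_strands, form = form)
  data.frame(region = names(sequences) %||% as.character(seq_along(sequences)),
             pnlr = vapply(res, `[[`, 0, "pnlr"),
             log_pnlr = vapply(res, `[[`, 0, "log_pnlr"),
             best_offset = vapply(res, `[[`, 0L, "best_offset"),
             best_strand = vapply(res, `[[`, "", "best_strand"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Motif-score trend along a signal ranking
#'
#' Orders regions by a ranking signal (descending — rank 1 is the
#' strongest region), then fits a cubic smoothing spline of `log_pnlr`
#' against rank with the smoothing parameter chosen by ordinary
#' leave-one-out cross-validation (`smooth.spline(..., cv = TRUE)`), the
#' same automatic choice used for the published trend curves.
#'
#' @param log_pnlr Per-region log2 maximum NLR values.
#' @param ranking_values Signal used to rank regions (e.g. HIF-1beta RPKM).
#' @return List with `rank`, `order` (into the input), `fitted` (trend at
#'   each rank), `spar` (chosen smoothing parameter), `residual_sd`.
#' @export
motif_trend <- function(log_pnlr, ranking_values) {
  if (length(log_pnlr) != length(ranking_values))
    hif_stop("log_pnlr and ranking_values must align", "hif_validation_error")
  if (length(log_pnlr) < 10) hif_stop("need >= 10 regions", "hif_domain_error")
  if (length(unique(ranking_values)) == 1L)
    hif_stop("constant ranking values", "hif_domain_error")
  ord <- order(ranking_values, decreasing = TRUE)
  y <- log_pnlr[ord]
  rk <- seq_along(y)
  fit <- smooth.spline(rk, y, cv = TRUE, keep.data = FALSE)
  fitted <- predict(fit, rk)$y
  list(rank = rk, order = ord, fitted = fitted, spar = fit$spar,
       residual_sd = sd(y - fitted))
}

#' Differential distribution of motif scores between two site sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on `log_pnlr` values.
#' A rank test is used because maximum scores are heavy-tailed; the test
#' direction reports which set is shifted higher.
#'
#' @param setA,setB Numeric vectors of `log_pnlr` values (length >= 2 each).
#' @return List with `pvalue`, `direction` (`"A_higher"`, `"B_higher"`,
#'   `"none"`), and the location `shift` (median difference A - B).
#' @export
differential_motif_test <- function(setA, setB) {
  if (length(setA) < 2 || length(setB) < 2)
    hif_stop("both sets need >= 2 values", "hif_domain_error")
  wt <- suppressWarnings(wilcox.test(setA, setB, alternative = "two.sided"))
  shift <- median(setA) - median(setB)
  direction <- if (wt$p.value >= 1 || shift == 0) "none"
               else if (shift > 0) "A_higher" else "B_higher"
  list(pvalue = wt$p.value, direction = direction, shift = shift)
}
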