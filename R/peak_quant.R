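## Consensus peak definition, RPKM, background-percentile filtering,
## cross-condition scatter summaries and the PCA biplot.

#' Construct a signal matrix over peak regions
#'
#' @param regions A `genomic_intervals` object (rows).
#' @param values Nonnegative numeric matrix, regions x conditions (RPKM).
#' @param conditions Condition labels; default taken from `colnames(values)`.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(regions, values, conditions = colnames(values)) {
  stopifnot(inherits(regions, "genomic_intervals"))
  values <- as.matrix(values)
  if (nrow(values) != nrow(regions))
    hif_stop("values rows must match regions", "hif_validation_error")
  if (is.null(conditions) || length(conditions) != ncol(values))
    hif_stop("conditions must label every value column", "hif_validation_error")
  if (any(values < 0)) hif_stop("negative signal values", "hif_validation_error")
  colnames(values) <- conditions
  structure(list(regions = regions, conditions = conditions, values = values),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d regions x %d conditions (%s)\n",
              nrow(x$values), ncol(x$values), paste(x$conditions, collapse = ", ")))
  invisible(x)
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count / ((region_length/1000) * (library_size/1e6))`, the
#' depth- and length-normalized signal used throughout the pipeline.
#'
#' @param count Read count(s) in the region (vectorized).
#' @param region_length Region length in bp, > 0.
#' @param library_size Total mapped reads in the library, > 0.
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(100, 1000, 1e6)  # 100
#' @export
compute_rpkm <- function(count, region_length, library_size) {
  if (any(region_length <= 0)) hif_stop("region_length must be > 0", "hif_domain_error")
  if (any(library_size <= 0)) hif_stop("library_size must be > 0", "hif_domain_error")
  count / ((region_length / 1000) * (library_size / 1e6))
}

#' Dual-caller consensus peaks
#'
#' Keeps only base pairs supported by both callers: the result is the
#' bp-level intersection of the two (internally merged) interval sets,
#' sorted and merged. Peaks reported by one caller only are dropped.
#'
#' @param setA,setB `genomic_intervals` from the two peak callers.
#' @return A `genomic_intervals` object of consensus regions (summit =
#'   midpoint, since the callers' summits need not agree).
#' @export
consensus_peaks <- function(setA, setB) {
  stopifnot(inherits(setA, "genomic_intervals"), inherits(setB, "genomic_intervals"))
  if (nrow(setA) == 0 || nrow(setB) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  out <- lapply(sort(unique(intersect(setA$chrom, setB$chrom))), function(ch) {
    a <- setA[setA$chrom == ch, ]; b <- setB[setB$chrom == ch, ]
    # shift to 1-based closed for IRanges, back to BED on the way out
    ia <- IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end))
    ib <- IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end))
    ov <- IRanges::intersect(ia, ib)
    if (!length(ov)) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ov) - 1L, end = IRanges::end(ov))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(genomic_intervals(character(), numeric(), numeric()))
  genomic_intervals(out$chrom, out$start, out$end)
}

#' Background signal threshold at a tail probability
#'
#' Empirical upper quantile of per-region background totals: the smallest
#' background value such that at most `floor(n * p)` background regions
#' sit at or above it. With one million background regions and
#' `p = 1e-4` (the 99.99th percentile) about 100 background regions pass,
#' which is the calibration the quantitative peak filter relies on.
#'
#' @param background_values Per-region background totals.
#' @param p Tail probability in (0, 1); default `1e-4`.
#' @return Threshold value; peaks with total `>= threshold` are kept.
#' @export
background_threshold <- function(background_values, p = 1e-4) {
  background_values <- background_values[!is.na(background_values)]
  n <- length(background_values)
  if (n == 0) hif_stop("empty background", "hif_domain_error")
  if (p <= 0 || p >= 1) hif_stop("p must be in (0,1)", "hif_domain_error")
  if (n < 1 / p)
    warning(sprintf("only %d background values for tail p=%g; threshold is coarse", n, p))
  s <- sort(background_values)
  idx <- min(n, floor((1 - p) * n) + 1L)
  s[idx]
}

#' Quantitative peak filter against the background threshold
#'
#' @param peaks A `genomic_intervals` object.
#' @param totals Per-peak total signal, aligned with `peaks`.
#' @param threshold Value from [background_threshold()].
#' @return List with `peaks` (retained intervals), `kept` (logical mask)
#'   and `n_dropped`.
#' @export
filter_peaks <- function(peaks, totals, threshold) {
  stopifnot(inherits(peaks, "genomic_intervals"))
  if (length(totals) != nrow(peaks))
    hif_stop("totals must align with peaks", "hif_validation_error")
  kept <- !is.na(totals) & totals >= threshold
  hif_log("peak filter: retained %d / %d peaks at threshold %.4g",
          sum(kept), length(kept), threshold)
  list(peaks = peaks[kept, , drop = FALSE], kept = kept,
       n_dropped = sum(!kept))
}

#' Cross-condition signal scatter summary
#'
#' Pairs two conditions of a signal matrix, log-transforms
#' (`log2(x + 1)`), and reports Pearson and Spearman correlations plus the
#' fraction of sites above the equity line `y = x` (ties count as below),
#' the summary used to ask whether binding strength is preserved between
#' two cell states.
#'
#' @param mat A `signal_matrix`.
#' @param condX,condY Condition labels.
#' @param sites Optional integer/logical subset of regions.
#' @return List with `x`, `y` (log2 values), `pearson`, `spearman`,
#'   `fraction_above`, `n`, and `flag` (set when fewer than 3 sites).
#' @export
signal_scatter <- function(mat, condX, condY, sites = NULL) {
  stopifnot(inherits(mat, "signal_matrix"))
  for (cn in c(condX, condY)) if (!cn %in% mat$conditions)
    hif_stop(paste0("condition not present: ", cn), "hif_validation_error")
  v <- mat$values
  if (!is.null(sites)) v <- v[sites, , drop = FALSE]
  x <- log2(v[, condX] + 1); y <- log2(v[, condY] + 1)
  n <- length(x)
  if (n < 3) {
    return(list(x = x, y = y, pearson = NA_real_, spearman = NA_real_,
                fraction_above = if (n) mean(y > x) else NA_real_, n = n,
                flag = "fewer than 3 sites: correlation undefined"))
  }
  list(x = x, y = y,
       pearson = cor(x, y, method = "pearson"),
       spearman = cor(x, y, method = "spearman"),
       fraction_above = mean(y > x), n = n, flag = NULL)
}

#' PCA biplot of a signal matrix
#'
#' Works on `log2(x + 1)` signal with per-condition centering, then takes
#' the singular value decomposition of the centered matrix: site scores are
#' `U %*% D`, condition loadings are the right singular vectors, and
#' explained variance fractions are `d^2 / sum(d^2)`. Component signs are
#' fixed so the largest-magnitude loading of each component is positive.
#'
#' @param mat A `signal_matrix` (>= 3 regions, >= 2 conditions).
#' @param n_components Number of components to keep (default 2; `NULL`
#'   keeps all, in which case `scores %*% t(loadings)` reconstructs the
#'   centered matrix exactly).
#' @return List of class `pca_biplot` with `site_scores`,
#'   `condition_loadings`, `explained_variance`, `center`, and `degenerate`
#'   flag for constant input.
#' @export
pca_biplot <- function(mat, n_components = 2) {
  stopifnot(inherits(mat, "signal_matrix"))
  v <- log2(mat$values + 1)
  if (ncol(v) < 2) hif_stop("need >= 2 conditions", "hif_domain_error")
  if (nrow(v) < 3) hif_stop("need >= 3 regions", "hif_domain_error")
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  degenerate <- all(abs(vc) < 1e-12)
  sv <- svd(vc)
  k <- if (is.null(n_components)) length(sv$d) else min(n_components, length(sv$d))
  # sign convention: dominant loading of each component points up
  for (j in seq_along(sv$d)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) { sv$v[, j] <- -sv$v[, j]; sv$u[, j] <- -sv$u[, j] }
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  rownames(loadings) <- mat$conditions
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  ev <- if (sum(sv$d^2) > 0) sv$d^2 / sum(sv$d^2) else rep(0, length(sv$d))
  structure(list(site_scores = scores, condition_loadings = loadings,
                 explained_variance = ev[seq_len(k)], center = ctr,
                 degenerate = degenerate),
            class = "pca_biplot")
}
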