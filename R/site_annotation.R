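## Relating binding sites to genes: nearest-TSS links, gene-class
## breakdowns, isoform-specific classification, and windowed gene capture.
##
## Distances are summit-to-TSS (all motif and profile analyses are
## summit-centered) and signed so that positive = downstream of the TSS
## in the gene's reading direction.

#' Nearest TSS for each binding site
#'
#' For each site, finds the gene minimizing `|summit - tss|` on the same
#' chromosome. Equidistant candidates are broken by the lexicographically
#' smaller gene id (logged). Sites on a chromosome with no annotated gene
#' get an `NA` link, flagged.
#'
#' @param sites A `genomic_intervals` object.
#' @param annotation A `gene_annotation` object.
#' @return data.frame with one row per site: `site` (row index), `gene`,
#'   `gene_class`, `distance` (signed bp; positive = downstream of TSS
#'   after strand flip), `tie` (logical).
#' @export
nearest_tss <- function(sites, annotation) {
  stopifnot(inherits(sites, "genomic_intervals"), inherits(annotation, "gene_annotation"))
  if (nrow(annotation) == 0) hif_stop("empty annotation", "hif_domain_error")
  summit <- interval_summits(sites)
  n <- nrow(sites)
  gene <- gene_class <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  tie <- rep(FALSE, n)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    if (nrow(ann) == 0) next
    for (i in si) {
      d <- abs(summit[i] - ann$tss)
      best <- which(d == min(d))
      if (length(best) > 1) {
        tie[i] <- TRUE
        best <- best[order(ann$id[best])][1]
      }
      gene[i] <- ann$id[best]
      gene_class[i] <- ann$gene_class[best]
      raw <- summit[i] - ann$tss[best]
      distance[i] <- if (ann$strand[best] == "-") -raw else raw
    }
  }
  if (any(tie)) hif_log("nearest_tss: %d equidistant tie(s) broken by gene id", sum(tie))
  if (anyNA(gene)) hif_log("nearest_tss: %d site(s) on chromosomes with no gene", sum(is.na(gene)))
  data.frame(site = seq_len(n), gene = gene, gene_class = gene_class,
             distance = distance, tie = tie, stringsAsFactors = FALSE)
}

#' Gene-class breakdown of nearest-gene links
#'
#' @param links Output of [nearest_tss()].
#' @return List with `fractions` (named, summing to 1 over non-NA links)
#'   and `counts`.
#' @export
class_breakdown <- function(links) {
  cls <- links$gene_class[!is.na(links$gene_class)]
  if (!length(cls)) {
    warning("no linked sites: empty class breakdown")
    return(list(fractions = numeric(0), counts = integer(0)))
  }
  counts <- table(cls)
  list(fractions = setNames(as.numeric(counts) / sum(counts), names(counts)),
       counts = setNames(as.integer(counts), names(counts)))
}

#' Classify sites as isoform-specific or shared
#'
#' The fold difference between the two isoform signals is computed with a
#' pseudocount of 1 in numerator and denominator (`(v1 + 1)/(v2 + 1)`) so
#' unbound sites stay defined. A site is isoform-1 specific iff the fold
#' is at least `fold` (default 3, inclusive), isoform-2 specific iff it is
#' at most `1/fold`, and shared otherwise. Swapping the two conditions
#' swaps the specific calls and fixes shared calls (antisymmetry).
#'
#' @param mat A `signal_matrix`.
#' @param cond1,cond2 Condition labels for the two isoforms.
#' @param fold Fold-change boundary (inclusive), default 3.
#' @return data.frame with `site`, `fold` (pseudocounted v1/v2 ratio) and
#'   `call` in `{isoform1_specific, isoform2_specific, shared}`.
#' @export
classify_isoform_specific <- function(mat, cond1, cond2, fold = 3) {
  stopifnot(inherits(mat, "signal_matrix"))
  for (cn in c(cond1, cond2)) if (!cn %in% mat$conditions)
    hif_stop(paste0("condition not present: ", cn), "hif_validation_error")
  v1 <- mat$values[, cond1]; v2 <- mat$values[, cond2]
  fc <- (v1 + 1) / (v2 + 1)
  call <- ifelse(fc >= fold, "isoform1_specific",
          ifelse(fc <= 1 / fold, "isoform2_specific", "shared"))
  data.frame(site = seq_along(fc), fold = fc, call = call,
             stringsAsFactors = FALSE)
}

#' Genes within a window of a site summit
#'
#' @param site One-row `genomic_intervals` (or a row index plus the set).
#' @param annotation A `gene_annotation` object.
#' @param window Maximum `|summit - tss|` in bp (inclusive), default 10 kb.
#' @return The annotation rows within the window, sorted by distance.
#' @export
genes_within <- function(site, annotation, window = 10000) {
  stopifnot(inherits(site, "genomic_intervals"), inherits(annotation, "gene_annotation"))
  if (window <= 0) hif_stop("window must be > 0", "hif_domain_error")
  if (nrow(site) != 1) hif_stop("site must be a single interval", "hif_validation_error")
  summit <- interval_summits(site)
  ann <- annotation[annotation$chrom == site$chrom, , drop = FALSE]
  d <- abs(summit - ann$tss)
  keep <- which(d <= window)
  out <- ann[keep[order(d[keep])], , drop = FALSE]
  out$distance <- sort(d[keep])
  out
}

#' Histogram of signed TSS distances
#'
#' @param links Output of [nearest_tss()].
#' @param bin_edges Strictly increasing numeric vector of bin boundaries;
#'   distances outside the range are collected in open end bins.
#' @return List with `counts` (length `length(bin_edges) + 1`: underflow,
#'   the `length(bin_edges) - 1` closed bins, overflow) and `bin_edges`.
#' @export
tss_histogram <- function(links, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    hif_stop("bin_edges must be strictly increasing", "hif_validation_error")
  d <- links$distance[!is.na(links$distance)]
  k <- length(bin_edges)
  counts <- integer(k + 1)
  if (length(d)) {
    idx <- findInterval(d, bin_edges, rightmost.closed = TRUE) + 1L
    tab <- tabulate(idx, nbins = k + 1)
    counts <- as.integer(tab)
  }
  list(counts = counts, bin_edges = bin_edges)
}
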