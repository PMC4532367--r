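## Pre-ranked gene set enrichment: weighted Kolmogorov-Smirnov-style
## running sum with a gene-set permutation null. Phenotype permutation is
## unavailable by construction in pre-ranked mode, so the null is ES of
## random same-size gene sets drawn from the ranking universe.

#' Weighted enrichment score of a gene set against a ranking
#'
#' Walks down the ranked list; at a hit the running sum increments by
#' `|pi_i|^p / sum_hits(|pi|^p)`, at a miss it decrements by
#' `1/(N - k)`. The enrichment score is the running-sum value of largest
#' magnitude (sign retained). `weight_exponent = 1` is the classic
#' "weighted" statistic; 0 gives the unweighted Kolmogorov-Smirnov form.
#'
#' @param ranking A `ranked_gene_list` (or data.frame with `gene`, `pi`).
#' @param gene_set Character vector of member gene ids.
#' @param weight_exponent Hit-weight exponent p, default 1.
#' @return List with `es`, `running_sum` (length N), `hits` (logical along
#'   the ranking), `leading_edge` (gene ids up to the ES extremum).
#' @export
enrichment_score <- function(ranking, gene_set, weight_exponent = 1) {
  genes <- ranking$gene
  N <- length(genes)
  hits <- genes %in% gene_set
  k <- sum(hits)
  dropped <- length(setdiff(gene_set, genes))
  if (dropped) hif_log("enrichment_score: %d set member(s) outside the universe", dropped)
  if (k == 0) hif_stop("gene set disjoint from ranking universe", "hif_domain_error")
  if (k == N) hif_stop("gene set covers the whole universe", "hif_domain_error")
  w <- abs(ranking$pi)^weight_exponent
  inc <- ifelse(hits, w / sum(w[hits]), -1 / (N - k))
  if (sum(w[hits]) == 0)  # degenerate all-zero hit weights: fall back to equal steps
    inc[hits] <- 1 / k
  rs <- cumsum(inc)
  i_ext <- which.max(abs(rs))
  es <- rs[i_ext]
  leading <- if (es >= 0) genes[seq_len(i_ext)][hits[seq_len(i_ext)]]
             else genes[i_ext:N][hits[i_ext:N]]
  list(es = es, running_sum = rs, hits = hits, leading_edge = leading)
}

## ES only, for permutation loops: evaluates the running sum just before
## and just after each hit instead of materializing the full N-vector.
es_fast <- function(abs_w_pow, hit_idx, N) {
  k <- length(hit_idx)
  h <- sort.int(hit_idx)
  w <- abs_w_pow[h]
  sw <- sum(w)
  cw <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  d <- 1 / (N - k)
  after <- cw - (h - seq_len(k)) * d            # running sum just after hit i
  before <- c(0, cw[-k]) - (h - 1 - (seq_len(k) - 1)) * d  # just before hit i
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Permutation test for a gene-set enrichment score
#'
#' The null distribution is the ES of `n_perm` random gene sets of the
#' same size drawn uniformly from the ranking universe. The p-value uses
#' the add-one correction and counts null scores whose magnitude reaches
#' the observed `|ES|` (two-sided: under a symmetric null this p-value is
#' uniform, and it can never be 0); the normalized ES divides by the mean
#' magnitude of same-sign null scores. Use [two_tail_report()] when a
#' directional statement is wanted.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (default 10000; < 100 warns).
#' @param seed Integer seed; the result is deterministic given it.
#' @return List of class `enrichment_result` with `es`, `nes`, `pvalue`,
#'   `n_perm`, `running_sum`, `leading_edge`.
#' @export
gsea_permutation <- function(ranking, gene_set, n_perm = 10000, seed = 1,
                             weight_exponent = 1) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  obs <- enrichment_score(ranking, gene_set, weight_exponent)
  N <- nrow(ranking)
  k <- sum(obs$hits)
  aw <- abs(ranking$pi)^weight_exponent
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(j) {
    es_fast(aw, sample.int(N, k), N)
  }, 0)
  same_dir <- if (obs$es >= 0) null_es >= 0 else null_es < 0
  pvalue <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  denom <- mean(abs(null_es[same_dir]))
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
  structure(list(es = obs$es, nes = nes, pvalue = pvalue, n_perm = n_perm,
                 running_sum = obs$running_sum, leading_edge = obs$leading_edge,
                 null_es = null_es),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: ES=%.3f NES=%.3f p=%.4g (%d permutations)\n",
              x$es, x$nes, x$pvalue, x$n_perm))
  invisible(x)
}

#' Report enrichment separately for the two ends of the ranking
#'
#' Tests the gene set against the ranking as given (positive end: genes up
#' in the contrast) and against the reversed ranking (negative end), so
#' statements like "enriched among upregulated but not downregulated
#' genes" can be read off directly.
#'
#' @inheritParams gsea_permutation
#' @return List with `positive` and `negative`, each an
#'   `enrichment_result` restricted to that tail (p-value one-tailed via
#'   the sign-matched permutation count).
#' @export
two_tail_report <- function(ranking, gene_set, n_perm = 1000, seed = 1,
                            weight_exponent = 1) {
  pos <- gsea_permutation(ranking, gene_set, n_perm, seed, weight_exponent)
  rev_ranking <- ranking[rev(seq_len(nrow(ranking))), , drop = FALSE]
  neg <- gsea_permutation(rev_ranking, gene_set, n_perm, seed + 1, weight_exponent)
  tail_summary <- function(r) list(
    es = r$es, nes = r$nes,
    pvalue = if (r$es >= 0) r$pvalue else 1,  # only the enriched direction counts
    significant = r$es >= 0 && r$pvalue < 0.05
  )
  list(positive = tail_summary(pos), negative = tail_summary(neg))
}
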