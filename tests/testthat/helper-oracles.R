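# Independent brute-force oracles. These are deliberately naive (explicit
# loops, no shared code with R/) so they can vouch for the optimized
# implementations.

# Eq-style normalized likelihood ratio, explicit double loop
brute_nlr_profile <- function(sequence, probs, background,
                              form = c("mean", "product")) {
  form <- match.arg(form)
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(sequence, "")[[1]]
  L <- ncol(probs); W <- length(ch)
  out <- numeric(W - L + 1)
  for (j in seq_len(W - L + 1)) {
    vals <- numeric(L)
    ok <- TRUE
    for (i in seq_len(L)) {
      b <- match(ch[j + i - 1], bases)
      if (is.na(b)) { ok <- FALSE; break }
      vals[i] <- probs[b, i] / background[bases[b]]
    }
    out[j] <- if (!ok) 0
              else if (form == "mean") mean(vals)
              else prod(vals)^(1 / L)
  }
  out
}

brute_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# weighted running-sum enrichment score, explicit cumulative walk
brute_es <- function(pi_vals, hit_mask, p = 1) {
  N <- length(pi_vals)
  k <- sum(hit_mask)
  wsum <- sum(abs(pi_vals[hit_mask])^p)
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit_mask[i]) {
      if (wsum > 0) abs(pi_vals[i])^p / wsum else 1 / k
    } else -1 / (N - k)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# base-pair-level interval intersection on instances of modest size
brute_consensus <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  out <- NULL
  for (ch in sort(chroms)) {
    bp_a <- unlist(lapply(which(a$chrom == ch),
                          function(i) seq(a$start[i], a$end[i] - 1)))
    bp_b <- unlist(lapply(which(b$chrom == ch),
                          function(i) seq(b$start[i], b$end[i] - 1)))
    common <- sort(intersect(bp_a, bp_b))
    if (!length(common)) next
    brk <- c(0, which(diff(common) > 1), length(common))
    for (s in seq_len(length(brk) - 1)) {
      run <- common[(brk[s] + 1):brk[s + 1]]
      out <- rbind(out, data.frame(chrom = ch, start = run[1],
                                   end = run[length(run)] + 1))
    }
  }
  out
}

random_pwm <- function(L) {
  counts <- matrix(rpois(4 * L, 5) + runif(4 * L), 4, L)
  rownames(counts) <- c("A", "C", "G", "T")
  pwm_from_counts(counts, pseudocount = 0.25)
}

random_seq <- function(W) paste(sample(c("A", "C", "G", "T"), W, replace = TRUE),
                                collapse = "")

# exact PWM from probability columns (no pseudocount), for closed-form cases
pwm_exact <- function(cols) {
  m <- do.call(cbind, cols)
  rownames(m) <- c("A", "C", "G", "T")
  structure(m, class = "pwm")
}

uniform_bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

small_cohort <- function(n = 120, n_genes = 15, effect = 1, seed = 5) {
  set.seed(seed)
  z <- rnorm(n)
  load <- runif(n_genes, 0.5, 1) * sample(c(-1, 1), n_genes, replace = TRUE)
  x <- outer(z, load) + matrix(rnorm(n * n_genes), n, n_genes)
  colnames(x) <- sprintf("g%02d", seq_len(n_genes))
  tm <- rexp(n, 0.001 * exp(effect * z))
  cs <- rexp(n, 0.001)
  list(x = x, time = pmin(tm, cs), event = tm <= cs, z = z, loadings = load)
}
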