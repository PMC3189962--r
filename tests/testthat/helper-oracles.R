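# Independent brute-force oracles used to pin down the analytical code.

# Upper-tail hypergeometric by direct summation of choose() terms.
hyper_tail_oracle <- function(N, K, n, k) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sided Fisher p by exhaustive enumeration of tables with fixed margins
# (sum of probabilities of tables no more probable than the observed one).
fisher_two_sided_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; K <- a + c; N <- a + b + c + d; n <- K
  support <- max(0, m + K - N):min(m, K)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(N - m, K - x) / choose(N, K), 0)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive per-position motif scan, case- and mask-aware.
naive_scan <- function(seq, motif, both_strands = TRUE, respect_softmask = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  up <- toupper(chars)
  k <- nchar(motif)
  pats <- motif
  rc <- promobind::revcomp(motif)
  if (both_strands && rc != motif) pats <- c(pats, rc)
  hits <- integer(0)
  for (p0 in seq_len(length(chars) - k + 1)) {
    span <- p0:(p0 + k - 1)
    word <- paste(up[span], collapse = "")
    if (!word %in% pats) next
    if (respect_softmask && any(chars[span] %in% letters)) next
    hits <- c(hits, p0 - 1L)  # 0-based
  }
  hits
}

# Random soft-masked DNA string.
random_dna <- function(n, p_lower = 0.1, p_n = 0.02) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  low <- runif(n) < p_lower
  base[low] <- tolower(base[low])
  base[runif(n) < p_n] <- "N"
  paste(base, collapse = "")
}

# Brute-force strand-aware offset of a position from a TSS row.
offset_oracle <- function(center, pos, strand) {
  if (strand == "+") center - pos else pos - center
}

cobind_levels_for_test <- function() {
  c("unbound", "MYC-only", "single-MYC", "single+MYC", "multi-MYC", "multi+MYC")
}

# Small deterministic TSS/peak builders.
make_tss <- function(pos, strand = "+", chrom = "chr1",
                     gene = sprintf("g%d", seq_along(pos))) {
  promobind::tss_table(gene, chrom, pos, strand)
}

classify_from <- function(tss, otx2, myc, half_window = 2000) {
  oa <- promobind::assign_binding(otx2, tss, half_window)
  ma <- promobind::assign_binding(myc, tss, half_window)
  c(list(otx2_assign = oa, myc_assign = ma),
    promobind::classify_promoters(oa, ma, tss))
}
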