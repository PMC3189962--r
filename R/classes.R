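# Peak-to-promoter assignment, single/multiple classification, co-binding
# classes and hypergeometric enrichment.

#' Assign peaks to promoters by the +/- half-window center rule
#'
#' A peak is assigned to every promoter whose TSS lies within `half_window`
#' bp of the peak's center, i.e. with strand-aware offset in
#' \[-half_window, +half_window\], both endpoints inclusive. A peak may be
#' assigned to several promoters.
#'
#' @param peaks a peak table.
#' @param tss a TSS table.
#' @param half_window half-width of the binding window in bp.
#' @return `data.frame(tss_idx, gene_id, peak_idx, offset)`; `tss_idx` and
#'   `peak_idx` are row indices into `tss` and `peaks`.
#' @export
assign_binding <- function(peaks, tss, half_window = 2000) {
  common <- union(unique(tss$chrom), unique(peaks$chrom))
  wins <- GenomicRanges::GRanges(
    factor(tss$chrom, levels = common),
    IRanges::IRanges(start = pmax(1L, tss$position - half_window + 1L),
                     end = tss$position + half_window + 1L))
  pts <- GenomicRanges::GRanges(
    factor(peaks$chrom, levels = common),
    IRanges::IRanges(start = peaks$center + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, wins)
  ti <- S4Vectors::subjectHits(hits)
  pi <- S4Vectors::queryHits(hits)
  off <- relative_offset(peaks$center[pi], tss[ti, , drop = FALSE])
  keep <- abs(off) <= half_window  # inclusive at both endpoints
  data.frame(tss_idx = ti[keep], gene_id = tss$gene_id[ti[keep]],
             peak_idx = pi[keep], offset = off[keep],
             stringsAsFactors = FALSE)
}

#' Classify promoters by single/multiple binding and co-binding
#'
#' Counts assigned peaks of the primary ("OTX2-like") factor per promoter,
#' flags binding of the secondary ("MYC-like") factor, and derives the
#' six-way co-binding class: `unbound`, `MYC-only`, and the four classes of
#' primary-bound promoters (`single`/`multi` crossed with `+MYC`/`-MYC`).
#' Also tabulates counts and percentages over the stated denominators, and
#' the hypergeometric enrichment of secondary binding among
#' multiple-bound promoters against all promoters.
#'
#' @param otx2_assign,myc_assign assignments from [assign_binding()] for the
#'   two factors.
#' @param tss the TSS table both assignments refer to.
#' @return A list with `summaries` (one row per promoter: `gene_id`,
#'   `n_otx2_peaks`, `n_myc_peaks`, `myc_bound`, `otx2_class`,
#'   `cobind_class`) and `class_table` (counts, one-decimal percentages,
#'   enrichment p-value; full precision kept in `fractions`).
#' @export
classify_promoters <- function(otx2_assign, myc_assign, tss) {
  n <- nrow(tss)
  n_otx2 <- tabulate(otx2_assign$tss_idx, nbins = n)
  n_myc <- tabulate(myc_assign$tss_idx, nbins = n)
  myc_bound <- n_myc > 0
  otx2_class <- ifelse(n_otx2 == 0, "none",
                       ifelse(n_otx2 == 1, "single", "multiple"))
  cls <- ifelse(n_otx2 == 0, ifelse(myc_bound, "MYC-only", "unbound"),
                paste0(ifelse(n_otx2 == 1, "single", "multi"),
                       ifelse(myc_bound, "+MYC", "-MYC")))
  summaries <- data.frame(
    gene_id = tss$gene_id, chrom = tss$chrom, position = tss$position,
    n_otx2_peaks = n_otx2, n_myc_peaks = n_myc, myc_bound = myc_bound,
    otx2_class = otx2_class,
    cobind_class = factor(cls, levels = cobind_levels()),
    stringsAsFactors = FALSE)

  n_bound <- sum(n_otx2 > 0)
  n_single <- sum(n_otx2 == 1)
  n_multi <- sum(n_otx2 >= 2)
  n_mycb <- sum(myc_bound)
  n_cobound <- sum(n_otx2 > 0 & myc_bound)
  n_myc_single <- sum(n_otx2 == 1 & myc_bound)
  n_myc_multi <- sum(n_otx2 >= 2 & myc_bound)
  frac <- c(otx2_bound_of_total = n_bound / n,
            single_of_bound = if (n_bound) n_single / n_bound else 0,
            multiple_of_bound = if (n_bound) n_multi / n_bound else 0,
            myc_of_total = n_mycb / n,
            cobound_of_total = n_cobound / n,
            myc_given_single = if (n_single) n_myc_single / n_single else 0,
            myc_given_multiple = if (n_multi) n_myc_multi / n_multi else 0)
  class_table <- list(
    counts = c(total = n, otx2_bound = n_bound, single = n_single,
               multiple = n_multi, myc_bound = n_mycb, cobound = n_cobound,
               myc_and_single = n_myc_single, myc_and_multiple = n_myc_multi),
    fractions = frac,
    percent = round(100 * frac, 1),
    enrichment_p = if (n_multi > 0 && n_mycb > 0)
      hypergeometric_enrichment(n, n_mycb, n_multi, n_myc_multi) else NA_real_)
  class(class_table) <- "class_table"
  list(summaries = summaries, class_table = class_table)
}

#' @export
print.class_table <- function(x, ...) {
  cat("Promoter co-binding class table\n")
  print(x$counts)
  cat("percent:\n")
  print(x$percent)
  cat(sprintf("enrichment P(X >= k) = %.3g\n", x$enrichment_p))
  invisible(x)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Exact `P(X >= k)` for X hypergeometric(`N`, `K`, `n`): the probability of
#' observing at least `k` successes in a sample of `n` drawn without
#' replacement from a population of `N` containing `K` successes. Computed
#' as a log-space sum of `lchoose` terms so extreme tails (p ~ 1e-80) keep
#' full relative precision.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k observed successes (included in the tail).
#' @param log10_p if `TRUE`, return log10 of the probability.
#' @return The upper-tail probability (or its log10).
#' @examples
#' hypergeometric_enrichment(10, 5, 4, 3)  # 55/210
#' @export
hypergeometric_enrichment <- function(N, K, n, k, log10_p = FALSE) {
  if (!(k >= 0 && k <= n && n <= N && k <= K && K <= N))
    stop("require 0 <= k <= n <= N and k <= K <= N")
  i <- k:min(n, K)
  if (length(i) == 0 || k > min(n, K)) return(if (log10_p) -Inf else 0)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  ls <- m + log(sum(exp(lt - m)))
  if (log10_p) ls / log(10) else min(1, exp(ls))
}
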