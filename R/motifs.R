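# Fixed-motif scanning against soft-masked sequence, motif density
# profiles, motif frequency vs expression, and iterative exhaustive k-mer
# enrichment (the inner motif search is exact enumeration; at k <= 8
# exhaustive counting dominates any heuristic search).

#' Reverse complement of DNA strings
#' @param x character vector over the IUPAC-lite alphabet `A,C,G,T,N`
#'   (case preserved).
#' @return Reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtNn", "TGCAtgcaNn",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

#' Default OTX2-family binding motifs (homeodomain TAATCC family)
#' @return Character vector `TAATCC, TAAGCC, TAATCT`.
#' @export
otx2_motifs <- function() c("TAATCC", "TAAGCC", "TAATCT")

#' Default E-box motif set
#' @param extended if `TRUE`, the full CANNTG expansion instead of the
#'   canonical CACGTG.
#' @return Character vector of E-box motifs.
#' @export
ebox_motifs <- function(extended = FALSE) {
  if (!extended) return("CACGTG")
  nts <- c("A", "C", "G", "T")
  as.vector(outer(nts, nts, function(a, b) paste0("CA", a, b, "TG")))
}

validate_motifs <- function(motifs) {
  stopifnot(is.character(motifs), length(motifs) > 0, all(nzchar(motifs)))
  if (any(grepl("[^ACGT]", motifs)))
    stop("motifs must be uppercase over A,C,G,T")
  motifs
}

#' Scan a genome region for exact motif occurrences
#'
#' Finds all exact matches of each motif, and of its reverse complement
#' when `both_strands` is `TRUE`, inside `[start, end)` of a chromosome.
#' Overlapping occurrences are all reported; reverse-strand hits are mapped
#' to the forward coordinate of their first base; a palindromic motif is
#' counted once per position. With `respect_softmask`, matches overlapping
#' any lowercase (soft-masked) base are skipped.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region; defaults to the whole
#'   chromosome.
#' @param motifs character vector of uppercase motifs.
#' @param both_strands scan the reverse complement too.
#' @param respect_softmask skip matches overlapping lowercase bases.
#' @return `data.frame(motif, position, strand)` with 0-based forward
#'   genomic positions of match starts.
#' @examples
#' g <- c(chr1 = "GGTAATCCA")
#' scan_motif(g, "chr1", motifs = "TAATCC")$position  # 2
#' @export
scan_motif <- function(genome, chrom, start = 0, end = NULL,
                       motifs = otx2_motifs(), both_strands = TRUE,
                       respect_softmask = FALSE) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (is.null(end)) end <- L
  if (start < 0 || end > L || start >= end)
    stop("region [", start, ", ", end, ") out of bounds for ", chrom)
  validate_motifs(motifs)
  region <- substr(genome[[chrom]], start + 1L, end)
  up <- toupper(region)
  lower_cum <- cumsum(strsplit(region, "")[[1]] %in% letters)
  masked_span <- function(pos0, k) {
    # pos0 region-relative 0-based; TRUE if any base in span is lowercase
    (lower_cum[pos0 + k] - if (pos0 > 0) lower_cum[pos0] else 0) > 0
  }
  find_all <- function(pat) {
    m <- gregexpr(pat, up, fixed = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  out <- lapply(motifs, function(mo) {
    k <- nchar(mo)
    fwd <- find_all(mo)
    res <- data.frame(motif = character(0), position = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
    if (length(fwd))
      res <- data.frame(motif = mo, position = fwd, strand = "+",
                        stringsAsFactors = FALSE)
    if (both_strands) {
      rc <- revcomp(mo)
      if (rc != mo) {  # palindromes counted once
        rev_hits <- find_all(rc)
        if (length(rev_hits))
          res <- rbind(res, data.frame(motif = mo, position = rev_hits,
                                       strand = "-", stringsAsFactors = FALSE))
      }
    }
    if (respect_softmask && nrow(res) > 0)
      res <- res[!vapply(res$position, masked_span, TRUE, k = k), , drop = FALSE]
    res
  })
  res <- do.call(rbind, out)
  res <- res[order(res$motif, res$position), , drop = FALSE]
  res$position <- res$position + start
  rownames(res) <- NULL
  res
}

#' Motif density relative to TSSs or peak centers
#'
#' Per 50 bp bin, the percentage of anchors whose window contains at least
#' one occurrence (of any motif in the set) starting in that bin, plus an
#' occurrence-count-per-bp variant. TSS anchors use signed strand-aware
#' offsets; peak-center anchors use unsigned |offset| bins.
#'
#' @param genome named character vector of chromosome sequences.
#' @param anchors a TSS table (signed profile) or a peak table (unsigned,
#'   anchored at `center`).
#' @param motifs character vector of motifs, scanned as one family.
#' @param window offsets `c(lower, upper)`; for peak anchors use
#'   `c(0, upper)`.
#' @param bin_width bin width in bp.
#' @param masked skip occurrences overlapping soft-masked bases.
#' @param both_strands scan both strands.
#' @return A `binned_profile` of kind `"motif_percent"` with an extra
#'   element `count_per_bp`.
#' @export
motif_density_profile <- function(genome, anchors, motifs = otx2_motifs(),
                                  window = c(-5000, 3000), bin_width = 50,
                                  masked = FALSE, both_strands = TRUE) {
  if (nrow(anchors) == 0) stop("anchors must be non-empty")
  check_window(window, bin_width)
  validate_motifs(motifs)
  signed <- "strand" %in% names(anchors)
  pos <- if (signed) anchors$position else anchors$center
  nb <- (window[2] - window[1]) %/% bin_width
  hit_count <- integer(nb)
  occ_count <- integer(nb)
  kmax <- max(nchar(motifs))
  for (i in seq_len(nrow(anchors))) {
    chrom <- anchors$chrom[i]
    L <- nchar(genome[[chrom]])
    if (signed && anchors$strand[i] == "-") {
      lo <- pos[i] - window[2] - kmax; hi <- pos[i] - window[1] + kmax
    } else if (signed) {
      lo <- pos[i] + window[1] - kmax; hi <- pos[i] + window[2] + kmax
    } else {
      lo <- pos[i] - window[2] - kmax; hi <- pos[i] + window[2] + kmax
    }
    lo <- max(0L, as.integer(lo)); hi <- min(L, as.integer(hi))
    if (hi <= lo) next
    occ <- scan_motif(genome, chrom, lo, hi, motifs,
                      both_strands = both_strands, respect_softmask = masked)
    if (nrow(occ) == 0) next
    klen <- nchar(occ$motif)
    off <- if (!signed) abs(occ$position + (klen - 1L) %/% 2L - pos[i])
      else if (anchors$strand[i] == "+") occ$position - pos[i]
      else pos[i] - occ$position - (klen - 1L)
    inwin <- off >= window[1] & off < window[2]
    if (!any(inwin)) next
    b <- offset_bin(off[inwin], window, bin_width)
    occ_count <- occ_count + tabulate(b, nbins = nb)
    hit_count <- hit_count + (tabulate(b, nbins = nb) > 0)
  }
  prof <- new_binned_profile("motif_percent", window, bin_width,
                             100 * hit_count / nrow(anchors), hit_count,
                             nrow(anchors))
  prof$count_per_bp <- occ_count / (nrow(anchors) * bin_width)
  prof
}

#' Motif frequency in peaks binned by associated gene expression
#'
#' Peaks are sorted by the expression of their associated gene (ascending)
#' and grouped into consecutive bins of `bin_size`; the final partial bin
#' is kept and flagged. Per bin: mean expression and the fraction of peaks
#' containing at least one motif occurrence within the peak interval.
#' Peaks whose gene has no expression record are dropped with a message.
#'
#' @param peaks a peak table with a `gene_id` column (or supply
#'   `gene_ids`).
#' @param genome named character vector of chromosome sequences.
#' @param expression an expression table.
#' @param motifs character vector of motifs (one family).
#' @param bin_size peaks per bin.
#' @param gene_ids optional gene per peak, overriding `peaks$gene_id`.
#' @param masked skip soft-masked occurrences.
#' @return `data.frame(bin, n_peaks, mean_expression, motif_frequency,
#'   partial)`.
#' @export
motif_frequency_vs_expression <- function(peaks, genome, expression,
                                          motifs = otx2_motifs(),
                                          bin_size = 400, gene_ids = NULL,
                                          masked = FALSE) {
  if (is.null(gene_ids)) gene_ids <- peaks$gene_id
  if (is.null(gene_ids)) stop("peaks must carry gene_id (or pass gene_ids)")
  expr <- expression$expression[match(gene_ids, expression$gene_id)]
  drop <- is.na(expr)
  if (any(drop))
    message(sum(drop), " peak(s) dropped: no expression record for their gene")
  peaks <- peaks[!drop, , drop = FALSE]
  expr <- expr[!drop]
  ord <- order(expr)
  peaks <- peaks[ord, , drop = FALSE]
  expr <- expr[ord]
  n <- nrow(peaks)
  has_motif <- vapply(seq_len(n), function(i) {
    occ <- scan_motif(genome, peaks$chrom[i], peaks$start[i], peaks$end[i],
                      motifs, respect_softmask = masked)
    nrow(occ) > 0
  }, TRUE)
  bin <- (seq_len(n) - 1L) %/% bin_size + 1L
  out <- data.frame(
    bin = sort(unique(bin)),
    n_peaks = as.integer(table(bin)),
    mean_expression = as.numeric(tapply(expr, bin, mean)),
    motif_frequency = as.numeric(tapply(has_motif, bin, mean)))
  out$partial <- out$n_peaks < bin_size
  out
}

# ---- iterative exhaustive k-mer enrichment --------------------------------

count_kmers_one <- function(seq_up, k) {
  n <- nchar(seq_up)
  if (n < k) return(character(0))
  kmers <- substring(seq_up, 1:(n - k + 1), k:n)
  kmers[!grepl("N", kmers, fixed = TRUE)]
}

# both-strand counts: occurrences of each k-mer in the sequences and their
# reverse complements (so counts are symmetric under reverse complement);
# a palindromic k-mer's site is seen on both strands, so its count is
# halved to count each physical site once, matching scan_motif()
count_kmers <- function(seqs, k) {
  fwd <- unlist(lapply(toupper(seqs), count_kmers_one, k = k))
  rev <- unlist(lapply(toupper(revcomp(seqs)), count_kmers_one, k = k))
  both <- table(c(fwd, rev))
  pal <- names(both)[names(both) == revcomp(names(both))]
  both[pal] <- both[pal] / 2
  list(fwd = table(fwd), both = both,
       total_both = length(fwd) + length(rev))
}

#' Iterative exhaustive k-mer enrichment with masking
#'
#' Per round, all k-mers of the stated lengths are counted exhaustively on
#' both strands in foreground and background; the k-mer maximizing the
#' pseudocounted log2 relative-frequency ratio is reported, then all its
#' occurrences (and of its reverse complement) in the foreground are
#' replaced by `N`, and the procedure repeats. Reverse-complement pairs
#' score identically; the reported representative is the member with more
#' forward-strand foreground occurrences, then the lexicographically
#' smaller. Remaining ties across different k-mers break lexicographically.
#'
#' @param foreground,background character vectors of DNA sequences (e.g.
#'   peak sequences vs peak-flanking sequences).
#' @param lengths k-mer lengths to enumerate.
#' @param rounds number of mask-and-repeat rounds.
#' @param pseudocount added to counts and totals in the frequency ratio.
#' @return `data.frame(round, kmer, length, fg_count, bg_count, score)`;
#'   stops early with a warning if the foreground is exhausted.
#' @export
kmer_enrichment_iterative <- function(foreground, background,
                                      lengths = c(6, 7, 8), rounds = 15,
                                      pseudocount = 1) {
  stopifnot(length(foreground) > 0, length(background) > 0)
  fg <- toupper(foreground)
  bg_counts <- lapply(lengths, function(k) count_kmers(background, k))
  names(bg_counts) <- as.character(lengths)
  out <- list()
  for (r in seq_len(rounds)) {
    best <- NULL
    for (k in lengths) {
      fgc <- count_kmers(fg, k)
      if (fgc$total_both == 0) next
      bgc <- bg_counts[[as.character(k)]]
      km <- names(fgc$both)
      fg_n <- as.numeric(fgc$both)
      bg_n <- as.numeric(bgc$both[km])
      bg_n[is.na(bg_n)] <- 0
      score <- log2((fg_n + pseudocount) / (fgc$total_both + pseudocount)) -
        log2((bg_n + pseudocount) / (bgc$total_both + pseudocount))
      fwd_n <- as.numeric(fgc$fwd[km])
      fwd_n[is.na(fwd_n)] <- 0
      # order: score desc, forward-strand count desc, lexicographic
      ord <- order(-score, -fwd_n, km)[1]
      cand <- list(kmer = km[ord], length = k, fg_count = fg_n[ord],
                   bg_count = bg_n[ord], score = score[ord],
                   fwd = fwd_n[ord])
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$fwd > best$fwd) ||
          (cand$score == best$score && cand$fwd == best$fwd &&
             cand$kmer < best$kmer))
        best <- cand
    }
    if (is.null(best)) {
      warning("foreground exhausted after ", r - 1L, " round(s)")
      break
    }
    out[[r]] <- data.frame(round = r, kmer = best$kmer, length = best$length,
                           fg_count = best$fg_count, bg_count = best$bg_count,
                           score = best$score, stringsAsFactors = FALSE)
    mask <- strrep("N", best$length)
    fg <- gsub(best$kmer, mask, fg, fixed = TRUE)
    rc <- revcomp(best$kmer)
    if (rc != best$kmer) fg <- gsub(rc, mask, fg, fixed = TRUE)
  }
  do.call(rbind, out)
}
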