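test_that("motif scanning handles strands, palindromes and soft-masking", {
  g <- c(chr1 = "GGTAATCCA")
  hits <- scan_motif(g, "chr1", motifs = "TAATCC")
  expect_equal(hits$position, 2L)
  expect_equal(hits$strand, "+")

  # reverse-complement hit reported at its forward first base
  g <- c(chr1 = "GGATTA")
  hits <- scan_motif(g, "chr1", motifs = "TAATCC")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "-")
  expect_equal(nrow(scan_motif(g, "chr1", motifs = "TAATCC",
                               both_strands = FALSE)), 0L)

  # soft-mask semantics
  g <- c(chr1 = "ggtaatcca")
  expect_equal(nrow(scan_motif(g, "chr1", motifs = "TAATCC",
                               respect_softmask = TRUE)), 0L)
  expect_equal(nrow(scan_motif(g, "chr1", motifs = "TAATCC",
                               respect_softmask = FALSE)), 1L)

  # palindromic motif counted once per position
  g <- c(chr1 = "ACACGTGT")
  expect_equal(nrow(scan_motif(g, "chr1", motifs = "CACGTG")), 1L)

  expect_error(scan_motif(g, "chr1", start = 0, end = 100), "out of bounds")
  expect_error(scan_motif(g, "chrX", motifs = "TAATCC"), "unknown chromosome")
  expect_error(scan_motif(g, "chr1", motifs = "taatcc"), "uppercase")
})

test_that("scanning equals the naive per-position oracle on random strings", {
  withr::local_seed(71)
  motifs <- c("TAATCC", "CACGTG", "TTAA")
  for (rep in 1:12) {
    s <- random_dna(sample(100:2000, 1))
    g <- c(chrT = s)
    for (mo in motifs) for (mask in c(FALSE, TRUE)) {
      got <- scan_motif(g, "chrT", motifs = mo, respect_softmask = mask)
      expect_equal(got$position, naive_scan(s, mo, respect_softmask = mask),
                   info = sprintf("motif=%s mask=%s rep=%d", mo, mask, rep))
    }
  }
})

test_that("masked occurrence counts never exceed unmasked counts", {
  ds <- generate_dataset(synthetic_config(n_promoters = 60, seed = 81),
                         what = "sequence")
  chr <- names(ds$genome)[1]
  um <- scan_motif(ds$genome, chr, motifs = otx2_motifs(), respect_softmask = FALSE)
  ma <- scan_motif(ds$genome, chr, motifs = otx2_motifs(), respect_softmask = TRUE)
  expect_lte(nrow(ma), nrow(um))
  # masked hits are a subset of unmasked hits
  expect_true(all(paste(ma$motif, ma$position) %in% paste(um$motif, um$position)))
  # on mask-free sequence the two scans agree
  clean <- c(chrC = toupper(ds$genome[[chr]]))
  expect_equal(nrow(scan_motif(clean, "chrC", motifs = otx2_motifs(),
                               respect_softmask = TRUE)),
               nrow(scan_motif(clean, "chrC", motifs = otx2_motifs(),
                               respect_softmask = FALSE)))
})

test_that("density profile localizes a motif planted at a fixed TSS offset", {
  n <- 30
  pos <- seq(10000, by = 10000, length.out = n)
  strand <- rep(c("+", "-"), length.out = n)
  L <- max(pos) + 10000
  seqv <- rep("A", L)  # poly-A background: no spurious TAATCC either strand
  for (i in seq_len(n)) {
    m <- if (strand[i] == "+") "TAATCC" else promobind::revcomp("TAATCC")
    g0 <- if (strand[i] == "+") pos[i] - 275 else pos[i] + 275 - 5
    seqv[(g0 + 1):(g0 + 6)] <- strsplit(m, "")[[1]]
  }
  g <- c(chr1 = paste(seqv, collapse = ""))
  tss <- make_tss(pos, strand = strand)
  prof <- motif_density_profile(g, tss, motifs = "TAATCC",
                                window = c(-1000, 1000))
  expect_equal(prof$values[prof$centers == -275], 100)
  expect_true(all(prof$values[prof$centers != -275] == 0))
  # anchor order does not matter
  prof2 <- motif_density_profile(g, tss[sample(n), ], motifs = "TAATCC",
                                 window = c(-1000, 1000))
  expect_equal(prof2$values, prof$values)
})

test_that("motif frequency vs expression bins peaks by expression rank", {
  n <- 800
  pos <- seq(5000, by = 2000, length.out = n)
  # motif inside the 400 lowest-expression peaks only
  seqv <- rep("A", max(pos) + 3000)
  expr <- expression_table(sprintf("g%d", 1:n), seq(0, 8, length.out = n))
  for (i in 1:400) seqv[(pos[i] + 1):(pos[i] + 6)] <- strsplit("TAATCC", "")[[1]]
  g <- c(chr1 = paste(seqv, collapse = ""))
  pk <- peak_table("chr1", pos - 100, pos + 100)
  pk$gene_id <- sprintf("g%d", 1:n)
  out <- motif_frequency_vs_expression(pk, g, expr, motifs = "TAATCC")
  expect_equal(out$motif_frequency, c(1, 0))
  expect_equal(out$partial, c(FALSE, FALSE))
  expect_lt(out$mean_expression[1], out$mean_expression[2])

  # final partial bin kept and flagged; unmapped peaks dropped with a message
  out399 <- motif_frequency_vs_expression(pk[1:399, ], g, expr, motifs = "TAATCC")
  expect_equal(nrow(out399), 1L)
  expect_true(out399$partial)
  expr_miss <- expression_table(sprintf("g%d", 3:n), seq_len(n - 2))
  expect_message(
    motif_frequency_vs_expression(pk, g, expr_miss, motifs = "TAATCC"),
    "2 peak")
})

test_that("iterative k-mer enrichment recovers planted motifs in rate order", {
  withr::local_seed(91)
  mk_seqs <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  plant <- function(seqs, motif, rate) {
    hit <- seq_len(floor(rate * length(seqs)))
    for (i in hit) {
      at <- sample(nchar(seqs[i]) - nchar(motif), 1)
      substr(seqs[i], at, at + nchar(motif) - 1) <- motif
    }
    seqs
  }
  scrub <- function(seqs, motif) {
    # remove chance occurrences so the planted motifs are absent from bg
    seqs <- gsub(motif, strrep("A", nchar(motif)), seqs, fixed = TRUE)
    gsub(promobind::revcomp(motif), strrep("A", nchar(motif)), seqs, fixed = TRUE)
  }
  bg <- scrub(scrub(mk_seqs(150, 120), "TAATCC"), "CACGTG")
  fg <- plant(plant(scrub(scrub(mk_seqs(150, 120), "TAATCC"), "CACGTG"),
                    "TAATCC", 0.6), "CACGTG", 0.3)
  res <- kmer_enrichment_iterative(fg, bg, rounds = 3)
  expect_equal(res$kmer[1], "TAATCC")
  expect_true("CACGTG" %in% res$kmer[1:2])
  expect_true(all(diff(res$round) > 0))
  # deterministic: identical inputs give the identical round list
  expect_identical(res, kmer_enrichment_iterative(fg, bg, rounds = 3))

  # null case: identical foreground and background score ~ 0
  res0 <- kmer_enrichment_iterative(bg, bg, rounds = 1)
  expect_lt(abs(res0$score[1]), 0.05)

  # exhausted foreground stops early with a warning
  expect_warning(
    kmer_enrichment_iterative("NNNNNNNNNN", bg, lengths = 6, rounds = 2),
    "exhausted")
})
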