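# Readers/writers for the plain-text interchange formats. All coordinates
# 0-based half-open on disk (BED/bedGraph convention).

read_delim_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
}

#' Read peaks from a BED-like file
#'
#' At least three whitespace-separated columns (chrom, start, end) with an
#' optional fourth score column interpreted as the log2 peak signal. Missing
#' scores become 0. Centers are computed as `floor((start + end)/2)`.
#'
#' @param path file path.
#' @param factor_label factor name attached to every peak.
#' @return A peak table (see [peak_table()]).
#' @export
read_peaks <- function(path, factor_label = "TF") {
  lines <- read_delim_lines(path)
  if (length(lines) == 0L)
    return(peak_table(character(), integer(), integer(), factor_label = factor_label))
  fields <- strsplit(lines, "[ \t]+")
  n <- vapply(fields, length, 1L)
  if (any(n < 3L))
    stop("malformed BED line ", which(n < 3L)[1], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop("malformed BED line ", which(bad)[1], ": non-integer coordinates")
  bad <- end <= start
  if (any(bad))
    stop("malformed BED line ", which(bad)[1], ": end <= start")
  signal <- vapply(seq_along(fields), function(i)
    if (n[i] >= 4L) suppressWarnings(as.numeric(fields[[i]][4L])) else 0, 0)
  signal[is.na(signal)] <- 0
  peak_table(chrom, start, end, signal, factor_label)
}

#' Write peaks to a BED-like file
#'
#' Inverse of [read_peaks()]: coordinates and scores round-trip bit-exactly.
#'
#' @param peaks a peak table.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.17g",
                     peaks$chrom, peaks$start, peaks$end, peaks$signal), path)
  invisible(path)
}

#' Read a TSS table from a TSV file
#'
#' Columns: gene_id, chrom, position (0-based), strand.
#'
#' @param path file path.
#' @return A validated TSS table.
#' @export
read_tss <- function(path) {
  x <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                  col.names = c("gene_id", "chrom", "position", "strand"),
                  colClasses = c("character", "character", "integer", "character"))
  validate_tss(x)
}

#' Write a TSS table to TSV
#' @param tss a TSS table.
#' @param path output path.
#' @export
write_tss <- function(tss, path) {
  writeLines(sprintf("%s\t%s\t%d\t%s", tss$gene_id, tss$chrom,
                     tss$position, tss$strand), path)
  invisible(path)
}

#' Read an expression table (gene_id, log2 expression) from TSV
#'
#' Duplicate gene identifiers are an error.
#'
#' @param path file path.
#' @return An expression table.
#' @export
read_expression <- function(path) {
  x <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                  col.names = c("gene_id", "expression"),
                  colClasses = c("character", "numeric"))
  expression_table(x$gene_id, x$expression)
}

#' Write an expression table to TSV
#' @param expr an expression table.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  writeLines(sprintf("%s\t%.17g", expr$gene_id, expr$expression), path)
  invisible(path)
}

#' Read a probe-level signal track from a bedGraph-like file
#'
#' Columns chrom, start, end, value; single-position probes use
#' `end = start + 1` and the probe position is `start`.
#'
#' @param path file path.
#' @return A signal track (see [signal_track()]).
#' @export
read_signal_track <- function(path) {
  x <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                  col.names = c("chrom", "start", "end", "value"),
                  colClasses = c("character", "integer", "integer", "numeric"))
  signal_track(x$chrom, x$start, x$value)
}

#' Write a signal track as bedGraph (single-position probes)
#' @param track a signal track.
#' @param path output path.
#' @export
write_signal_track <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%.17g", track$chrom, track$position,
                     track$position + 1L, track$value), path)
  invisible(path)
}

#' Read a soft-masked genome from FASTA
#'
#' Case is preserved: lowercase letters represent soft-masked (repeat)
#' sequence and are the only repeat-mask representation used by this
#' package.
#'
#' @param path FASTA file path.
#' @return Named character vector, one string per chromosome.
#' @export
read_genome_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  genome <- vapply(recs, function(s) as.character(s[[1]]), "")
  names(genome) <- names(recs)
  validate_genome(genome)
  genome
}

#' Write a soft-masked genome to FASTA
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  seqinr::write.fasta(as.list(genome), names = names(genome),
                      file.out = path, nbchar = 70)
  invisible(path)
}
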