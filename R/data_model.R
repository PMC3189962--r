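#' promobind: promoter binding landscapes for paired transcription factors
#'
#' Tools to characterize where transcription factors bind relative to
#' transcription start sites (TSSs), classify promoters by single/multiple
#' binding and co-binding of two factors, test peak-peak proximity against a
#' randomization null, scan binding motifs against soft-masked genome
#' sequence, and relate binding classes to gene expression.
#'
#' Coordinate conventions: all genomic coordinates are 0-based, intervals are
#' half-open (BED convention); a TSS position is the first transcribed base.
#' TSS-relative offsets are strand-aware and negative upstream.
#'
#' @importFrom stats rnorm rgeom rpois runif fisher.test t.test
#'   setNames sd ave
#' @importFrom utils read.table write.table head tail
#' @keywords internal
"_PACKAGE"

# ---- domain-type constructors / validators -------------------------------

#' Construct and validate a TSS table
#'
#' One row per promoter region: the transcription start of a gene with its
#' strand. A gene may contribute several promoters (rows sharing `gene_id`).
#'
#' @param gene_id character, non-empty identifiers.
#' @param chrom character chromosome names.
#' @param position non-negative integer 0-based TSS coordinates (the first
#'   transcribed base).
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `position`,
#'   `strand`.
#' @export
tss_table <- function(gene_id, chrom, position, strand) {
  tss <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    position = as.integer(position),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  validate_tss(tss)
}

validate_tss <- function(tss) {
  stopifnot(is.data.frame(tss),
            all(c("gene_id", "chrom", "position", "strand") %in% names(tss)))
  if (any(is.na(tss$position)) || any(tss$position < 0))
    stop("TSS positions must be non-negative integers")
  bad <- !tss$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol: ", paste(unique(tss$strand[bad]), collapse = ", "))
  if (any(is.na(tss$gene_id)) || any(!nzchar(tss$gene_id)))
    stop("gene_id must be non-empty")
  tss
}

#' Construct and validate a peak table
#'
#' A called binding interval with its center (the field's standard location
#' summary) and a log2 signal, labeled by the immunoprecipitated factor.
#' Centers are `floor((start + end) / 2)`; even-width ties resolve by floor.
#'
#' @param chrom character chromosome names.
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param signal numeric log2 ratio per peak (default 0).
#' @param factor_label single string naming the factor (e.g. `"OTX2"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `center`,
#'   `signal`, `factor`.
#' @export
peak_table <- function(chrom, start, end, signal = 0, factor_label = "TF") {
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer coordinates in peak table")
  if (any(end <= start))
    stop("end <= start in peak table")
  data.frame(chrom = as.character(chrom),
             start = as.integer(start),
             end = as.integer(end),
             center = as.integer((as.numeric(start) + as.numeric(end)) %/% 2),
             signal = as.numeric(rep_len(signal, length(start))),
             factor = rep_len(as.character(factor_label), length(start)),
             stringsAsFactors = FALSE)
}

#' Construct and validate a probe-level signal track
#'
#' Ordered probe measurements (log2 ratios). Positions must be strictly
#' increasing within each chromosome.
#'
#' @param chrom,position,value parallel vectors of probe chromosome, 0-based
#'   position and log2 ratio.
#' @return A `data.frame` with columns `chrom`, `position`, `value`, sorted
#'   by chromosome then position.
#' @export
signal_track <- function(chrom, position, value) {
  trk <- data.frame(chrom = as.character(chrom),
                    position = as.integer(position),
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  trk <- trk[order(trk$chrom, trk$position), , drop = FALSE]
  rownames(trk) <- NULL
  dup <- stats::ave(trk$position, trk$chrom,
                    FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(dup > 0))
    stop("probe positions must be strictly increasing within a chromosome")
  trk
}

#' Construct and validate an expression table
#'
#' @param gene_id character identifiers, one record per gene.
#' @param expression numeric log2 expression values.
#' @return A `data.frame` with columns `gene_id`, `expression`.
#' @export
expression_table <- function(gene_id, expression) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in expression table: ",
         paste(head(unique(gene_id[duplicated(gene_id)]), 3), collapse = ", "))
  data.frame(gene_id = as.character(gene_id),
             expression = as.numeric(expression),
             stringsAsFactors = FALSE)
}

#' Validate a genome sequence object
#'
#' A genome is a named character vector, one string per chromosome, over
#' `A,C,G,T,N` where lowercase letters mark soft-masked (repeat) sequence.
#'
#' @param genome named character vector of chromosome sequences.
#' @return The validated genome (invisibly unchanged).
#' @export
validate_genome <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)), all(nzchar(names(genome))))
  for (chr in names(genome)) {
    if (grepl("[^ACGTNacgtn]", genome[[chr]]))
      stop("invalid nucleotide characters in chromosome ", chr)
  }
  invisible(genome)
}

# ---- offsets --------------------------------------------------------------

#' Strand-aware offset of a peak center relative to a TSS
#'
#' Signed base-pair offset of a position relative to a TSS, oriented along
#' the gene: negative values are upstream of the TSS regardless of strand.
#' On the plus strand the offset is `center - position`; on the minus strand
#' it is `position - center`.
#'
#' @param peak_center integer vector of 0-based peak-center coordinates.
#' @param tss a TSS table (or one row of one); recycled against
#'   `peak_center`.
#' @param peak_chrom optional chromosome of each peak; when supplied it must
#'   match the TSS chromosome.
#' @return Integer vector of signed offsets in bp.
#' @examples
#' tss <- tss_table("g", "chr1", 1000, "+")
#' relative_offset(750, tss)   # -250, upstream
#' @export
relative_offset <- function(peak_center, tss, peak_chrom = NULL) {
  if (!is.null(peak_chrom) && any(peak_chrom != tss$chrom))
    stop("chromosome mismatch between peak and TSS")
  as.integer(ifelse(tss$strand == "+",
                    peak_center - tss$position,
                    tss$position - peak_center))
}
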