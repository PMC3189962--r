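# TSS-anchored aggregate profiles. Bins are half-open [x, x+width) labeled
# by their center x + width/2; offset 0 falls in bin [0, width).

new_binned_profile <- function(kind, window, bin_width, values, n_informative,
                               n_promoters) {
  structure(list(kind = kind, window = window, bin_width = bin_width,
                 centers = seq(window[1], window[2] - bin_width, by = bin_width) +
                   bin_width / 2,
                 values = values, n_informative = n_informative,
                 n_promoters = n_promoters),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat(sprintf("<binned_profile> kind=%s window=[%d, %d) bin=%d bp, %d bins, n=%d\n",
              x$kind, x$window[1], x$window[2], x$bin_width,
              length(x$values), x$n_promoters))
  invisible(x)
}

check_window <- function(window, bin_width) {
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(lower, upper) with lower < upper")
  if ((window[2] - window[1]) %% bin_width != 0)
    stop("window width must be a multiple of bin_width")
}

# Pair every TSS with peaks/probes on its chromosome whose strand-aware
# offset lies in [window[1], window[2]). Returns (tss_idx, item_idx, offset).
window_pairs <- function(tss, chrom, position, window) {
  reach <- max(abs(window))
  common <- union(unique(tss$chrom), unique(chrom))
  wins <- GenomicRanges::GRanges(
    factor(tss$chrom, levels = common),
    IRanges::IRanges(start = pmax(1L, tss$position - reach + 1L),
                     end = tss$position + reach + 1L))
  pts <- GenomicRanges::GRanges(
    factor(chrom, levels = common),
    IRanges::IRanges(start = position + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(pts, wins)
  ti <- S4Vectors::subjectHits(hits)
  pi <- S4Vectors::queryHits(hits)
  off <- as.integer(ifelse(tss$strand[ti] == "+",
                           position[pi] - tss$position[ti],
                           tss$position[ti] - position[pi]))
  keep <- off >= window[1] & off < window[2]
  data.frame(tss_idx = ti[keep], item_idx = pi[keep], offset = off[keep])
}

offset_bin <- function(offset, window, bin_width) {
  (offset - window[1]) %/% bin_width + 1L
}

#' Discard closely spaced alternative TSSs of the same gene
#'
#' Within each gene, TSSs are scanned in genomic order and a TSS is dropped
#' when it lies fewer than `min_spacing` bp from the previously retained TSS
#' of that gene. Promoters of different genes are never compared.
#'
#' @param tss a TSS table.
#' @param min_spacing minimum spacing in bp (spacing exactly equal to it is
#'   kept).
#' @return The filtered TSS table.
#' @examples
#' tss <- tss_table(rep("g", 3), "chr1", c(0, 100, 400), "+")
#' filter_tss(tss)$position  # 0 and 400; 100 is too close to 0
#' @export
filter_tss <- function(tss, min_spacing = 150) {
  if (nrow(tss) == 0) return(tss)
  keep <- logical(nrow(tss))
  for (idx in split(seq_len(nrow(tss)), list(tss$gene_id, tss$chrom), drop = TRUE)) {
    idx <- idx[order(tss$position[idx])]
    last <- -Inf
    for (i in idx) {
      if (tss$position[i] - last >= min_spacing) {
        keep[i] <- TRUE
        last <- tss$position[i]
      }
    }
  }
  out <- tss[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean signal per 50 bp bin relative to the TSS
#'
#' Each probe is assigned to the bin containing its strand-aware offset from
#' each promoter whose window it falls in; the bin value is the mean over
#' all (probe, promoter) assignments pooled across promoters. Bins with no
#' data are `NA`.
#'
#' @param track a signal track.
#' @param tss a TSS table.
#' @param window offset window `c(lower, upper)`, half-open.
#' @param bin_width bin width in bp; the window must be a multiple of it.
#' @param per_promoter_first if `TRUE`, average per-promoter means instead
#'   of pooling all pairs.
#' @return A `binned_profile` of kind `"mean_signal"`.
#' @export
mean_signal_profile <- function(track, tss, window = c(-5000, 3000),
                                bin_width = 50, per_promoter_first = FALSE) {
  check_window(window, bin_width)
  nb <- (window[2] - window[1]) %/% bin_width
  pairs <- window_pairs(tss, track$chrom, track$position, window)
  bins <- offset_bin(pairs$offset, window, bin_width)
  vals <- track$value[pairs$item_idx]
  n_inf <- tabulate(bins, nbins = nb)
  if (per_promoter_first && nrow(pairs) > 0) {
    key <- paste(pairs$tss_idx, bins)
    pm <- tapply(vals, key, mean)
    pb <- as.integer(vapply(strsplit(names(pm), " "), `[[`, "", 2))
    sums <- tapply(as.numeric(pm), pb, sum)
    cnts <- tabulate(pb, nbins = nb)
    values <- rep(NA_real_, nb)
    values[as.integer(names(sums))] <- as.numeric(sums) /
      cnts[as.integer(names(sums))]
  } else {
    sums <- rep(0, nb)
    if (nrow(pairs) > 0) {
      agg <- rowsum(vals, bins)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    values <- ifelse(n_inf > 0, sums / pmax(n_inf, 1L), NA_real_)
  }
  new_binned_profile("mean_signal", window, bin_width, values, n_inf, nrow(tss))
}

#' Percentage of promoters with a peak per bin relative to the TSS
#'
#' Per bin, the percentage of promoters having at least one peak center
#' whose strand-aware offset falls in that bin; a promoter with several
#' peaks in one bin counts once there.
#'
#' @param peaks a peak table.
#' @param tss a TSS table.
#' @inheritParams mean_signal_profile
#' @return A `binned_profile` of kind `"percent_bound"` (values in
#'   \[0, 100\]).
#' @export
peak_frequency_profile <- function(peaks, tss, window = c(-5000, 3000),
                                   bin_width = 50) {
  check_window(window, bin_width)
  nb <- (window[2] - window[1]) %/% bin_width
  pairs <- window_pairs(tss, peaks$chrom, peaks$center, window)
  bins <- offset_bin(pairs$offset, window, bin_width)
  uniq <- !duplicated(cbind(pairs$tss_idx, bins))
  counts <- tabulate(bins[uniq], nbins = nb)
  values <- 100 * counts / max(nrow(tss), 1L)
  new_binned_profile("percent_bound", window, bin_width, values, counts, nrow(tss))
}

#' Detect local maxima of a binned profile
#'
#' Strict local maxima over the informative bins, with topographic
#' prominence above a threshold: the prominence of a candidate is its value
#' minus the highest of the key saddles separating it from higher bins (the
#' global maximum's prominence is its height above the profile minimum).
#' Plateaus of equal values resolve to the bin nearest the TSS.
#'
#' @param profile a `binned_profile` with at least 3 informative bins.
#' @param min_prominence prominence threshold; default 10% of the profile
#'   range.
#' @return `data.frame(offset, value)` sorted by offset (bin centers).
#' @export
find_profile_modes <- function(profile, min_prominence = NULL) {
  ok <- !is.na(profile$values)
  if (!any(ok)) stop("profile has no informative bins")
  if (sum(ok) < 3) stop("profile must have at least 3 informative bins")
  v <- profile$values[ok]
  centers <- profile$centers[ok]
  if (is.null(min_prominence))
    min_prominence <- 0.1 * diff(range(v))
  n <- length(v)

  # candidate runs of equal value strictly above both flanks
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_off <- numeric(0)
  out_val <- numeric(0)
  for (j in seq_along(r$values)) {
    left_ok <- starts[j] == 1L || v[starts[j] - 1L] < r$values[j]
    right_ok <- ends[j] == n || v[ends[j] + 1L] < r$values[j]
    if (!(left_ok && right_ok)) next
    val <- r$values[j]
    # topographic prominence: walk out to the nearest higher bin each side
    prom_side <- function(idx_seq) {
      if (length(idx_seq) == 0) return(min(v))
      key <- Inf
      for (i in idx_seq) {
        key <- min(key, v[i])
        if (v[i] > val) return(key)
      }
      min(v)  # no higher bin on this side
    }
    key_l <- prom_side(rev(seq_len(starts[j] - 1L)))
    key_r <- prom_side(if (ends[j] < n) (ends[j] + 1L):n else integer(0))
    prominence <- val - max(key_l, key_r)
    if (prominence <= 0 || prominence < min_prominence) next
    run_centers <- centers[starts[j]:ends[j]]
    out_off <- c(out_off, run_centers[which.min(abs(run_centers))])
    out_val <- c(out_val, val)
  }
  ord <- order(out_off)
  data.frame(offset = out_off[ord], value = out_val[ord])
}

#' Per-promoter binned signal matrix, sorted by an external key
#'
#' Rows are promoters (mean signal per bin, `NA` where no probe falls);
#' promoters with 100 or fewer informative bins inside the window are
#' excluded (the inclusion rule is strictly more than `min_informative`),
#' as are promoters with a missing sort key (with a message). Rows are
#' sorted by decreasing key; ties keep input order.
#'
#' @param track a signal track.
#' @param tss a TSS table.
#' @param sort_key numeric vector aligned with the rows of `tss` (e.g. log2
#'   expression of the corresponding gene).
#' @inheritParams mean_signal_profile
#' @param min_informative informative-bin threshold (strict).
#' @return A numeric matrix with promoter `gene_id` rownames and an
#'   attribute `"sort_key"` holding the recorded row order key.
#' @export
promoter_matrix <- function(track, tss, sort_key, window = c(-5000, 3000),
                            bin_width = 50, min_informative = 100) {
  check_window(window, bin_width)
  stopifnot(length(sort_key) == nrow(tss))
  nb <- (window[2] - window[1]) %/% bin_width
  pairs <- window_pairs(tss, track$chrom, track$position, window)
  bins <- offset_bin(pairs$offset, window, bin_width)
  mat <- matrix(NA_real_, nrow(tss), nb,
                dimnames = list(tss$gene_id, NULL))
  if (nrow(pairs) > 0) {
    key <- (bins - 1L) * nrow(tss) + pairs$tss_idx  # column-major linear index
    sums <- rowsum(track$value[pairs$item_idx], key)
    cnts <- rowsum(rep(1, length(key)), key)
    mat[as.integer(rownames(sums))] <- sums[, 1] / cnts[, 1]
  }
  informative <- rowSums(!is.na(mat))
  drop_na <- is.na(sort_key)
  if (any(drop_na))
    message(sum(drop_na), " promoter(s) excluded: missing sort key")
  keep <- informative > min_informative & !drop_na
  mat <- mat[keep, , drop = FALSE]
  key_kept <- sort_key[keep]
  ord <- order(-key_kept)  # stable radix order, ties keep input order
  mat <- mat[ord, , drop = FALSE]
  attr(mat, "sort_key") <- key_kept[ord]
  attr(mat, "bin_centers") <- seq(window[1], window[2] - bin_width,
                                  by = bin_width) + bin_width / 2
  mat
}

#' Principal upstream and downstream modes of a profile
#'
#' Convenience wrapper around [find_profile_modes()]: among detected modes,
#' returns the highest-valued mode upstream of the TSS (offset < 0) and the
#' highest-valued mode downstream (offset > 0), as bin-center offsets.
#'
#' Counting noise makes the raw argmax of a flat-topped peak jitter between
#' adjacent bins, so by default the location is refined as the value-weighted
#' centroid of the contiguous bins around the detected mode that stay above
#' half its height (the center of mass of the full-width-at-half-maximum
#' support, a standard peak-location estimator), snapped back to the nearest
#' bin center. Set `refine_frac = NULL` for the raw argmax bin.
#'
#' @inheritParams find_profile_modes
#' @param refine_frac height threshold for the centroid refinement, as a
#'   fraction of the mode height (default 0.5, half maximum), or `NULL` to
#'   disable.
#' @return `list(upstream, downstream)` of bin-center offsets (`NA` when no
#'   mode lies on that side).
#' @export
principal_modes <- function(profile, min_prominence = NULL, refine_frac = 0.5) {
  m <- find_profile_modes(profile, min_prominence)
  pick <- function(side) {
    mm <- m[side(m$offset), , drop = FALSE]
    if (nrow(mm) == 0) return(NA_real_)
    off <- mm$offset[which.max(mm$value)]
    if (is.null(refine_frac)) return(off)
    ok <- !is.na(profile$values)
    v <- profile$values[ok]
    centers <- profile$centers[ok]
    i <- which(centers == off)
    thr <- refine_frac * v[i]
    lo <- i; while (lo > 1 && v[lo - 1] >= thr) lo <- lo - 1
    hi <- i; while (hi < length(v) && v[hi + 1] >= thr) hi <- hi + 1
    centroid <- sum(centers[lo:hi] * v[lo:hi]) / sum(v[lo:hi])
    centers[which.min(abs(centers - centroid))]
  }
  list(upstream = pick(function(o) o < 0),
       downstream = pick(function(o) o > 0))
}
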