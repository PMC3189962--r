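# Observed vs randomized OTX2-MYC peak-center distances on single-OTX2
# promoters with MYC binding, and per-range Fisher exact enrichment.

#' Observed OTX2-MYC peak-center distances
#'
#' Restricted to promoters of class `single+MYC`: for each, the absolute
#' distance in bp between the single OTX2 peak center and the nearest
#' assigned MYC peak center.
#'
#' @param summaries per-promoter summaries from [classify_promoters()].
#' @param otx2_assign,myc_assign assignments from [assign_binding()].
#' @param otx2_peaks,myc_peaks the peak tables the assignments index into.
#' @return Integer vector of distances, named by promoter `gene_id`.
#' @export
observed_distances <- function(summaries, otx2_assign, myc_assign,
                               otx2_peaks, myc_peaks) {
  idx <- which(summaries$cobind_class == "single+MYC")
  otx2_by <- split(otx2_assign$peak_idx, otx2_assign$tss_idx)
  myc_by <- split(myc_assign$peak_idx, myc_assign$tss_idx)
  d <- vapply(idx, function(i) {
    oi <- otx2_by[[as.character(i)]]
    mi <- myc_by[[as.character(i)]]
    if (is.null(mi) || length(mi) == 0)
      stop("promoter ", summaries$gene_id[i],
           " flagged MYC-bound but has no assigned MYC peak")
    min(abs(otx2_peaks$center[oi[1]] - myc_peaks$center[mi]))
  }, 0)
  setNames(as.integer(d), summaries$gene_id[idx])
}

#' Randomization null for OTX2-MYC distances
#'
#' Per randomization, every OTX2 peak offset on a `single+MYC` promoter is
#' redrawn uniformly over the binding window \[-half_window, +half_window\]
#' (MYC peaks stay fixed, per-promoter OTX2 peak counts are preserved) and
#' nearest-MYC distances are recomputed. Deterministic given `seed`.
#'
#' @inheritParams observed_distances
#' @param R number of randomizations.
#' @param seed RNG seed.
#' @param half_window binding window half-width in bp.
#' @return A list of class `distance_null` with `pooled` (all null
#'   distances) and `per_randomization` (list of length `R`).
#' @export
randomized_null <- function(summaries, otx2_assign, myc_assign,
                            otx2_peaks, myc_peaks, R = 3, seed = 1,
                            half_window = 2000) {
  stopifnot(R >= 1)
  idx <- which(summaries$cobind_class == "single+MYC")
  myc_by <- split(myc_assign$peak_idx, myc_assign$tss_idx)
  # genomic offsets relative to the TSS; the redrawn uniform offset is
  # symmetric so strand orientation does not matter for |distance|
  myc_signed <- lapply(idx, function(i) {
    mi <- myc_by[[as.character(i)]]
    myc_peaks$center[mi] - summaries$position[i]
  })
  per <- with_seed(seed, lapply(seq_len(R), function(r) {
    u <- round(runif(length(idx), -half_window, half_window))
    vapply(seq_along(idx), function(j) min(abs(u[j] - myc_signed[[j]])), 0)
  }))
  structure(list(pooled = as.integer(unlist(per)),
                 per_randomization = lapply(per, as.integer), R = R),
            class = "distance_null")
}

#' Observed vs expected distance-range enrichment (Fisher's exact test)
#'
#' Distances are tallied into half-open ranges. Per range, a 2x2 table is
#' built from observed counts in/out of the range against null counts
#' scaled to the observed total (rounded to integers), and the two-sided
#' Fisher exact p-value (sum-of-smaller-probabilities rule) is computed.
#' Expected percentages are averaged over the individual randomizations.
#'
#' @param observed integer distances from [observed_distances()].
#' @param null a `distance_null` (or an integer vector treated as one
#'   pooled randomization).
#' @param breaks increasing lower bounds of the half-open ranges; an
#'   implicit final range extends to infinity. Default
#'   `c(0, 200, 400, 800, 1600)`.
#' @return A list of class `distance_result`: `ranges`, and a data.frame
#'   `table` with observed/expected counts, percentages and p-values.
#' @export
range_enrichment <- function(observed, null, breaks = c(0, 200, 400, 800, 1600)) {
  if (length(breaks) == 0) stop("empty range set")
  if (!inherits(null, "distance_null"))
    null <- structure(list(pooled = as.integer(null),
                           per_randomization = list(as.integer(null)), R = 1L),
                      class = "distance_null")
  if (length(observed) == 0 || length(null$pooled) == 0)
    stop("observed and null distance sets must be non-empty")
  edges <- c(breaks, Inf)
  n_r <- length(breaks)
  lab <- sprintf("[%s,%s)", edges[-length(edges)], edges[-1])
  bin_of <- function(d) findInterval(d, edges)  # ranges partition [0, Inf)
  obs_ct <- tabulate(bin_of(observed), nbins = n_r)
  null_prop <- tabulate(bin_of(null$pooled), nbins = n_r) / length(null$pooled)
  per_pct <- vapply(null$per_randomization, function(d)
    100 * tabulate(bin_of(d), nbins = n_r) / length(d), numeric(n_r))
  exp_pct <- if (n_r == 1) mean(per_pct) else rowMeans(per_pct)
  n_obs <- length(observed)
  exp_ct <- as.integer(round(null_prop * n_obs))
  p <- vapply(seq_len(n_r), function(i) {
    tab <- matrix(c(obs_ct[i], n_obs - obs_ct[i],
                    exp_ct[i], n_obs - exp_ct[i]), nrow = 2, byrow = TRUE)
    min(1, fisher.test(tab)$p.value)  # guard tiny >1 overshoot
  }, 0)
  structure(list(
    ranges = lab,
    n_observed = n_obs,
    table = data.frame(range = lab, observed = obs_ct,
                       observed_pct = 100 * obs_ct / n_obs,
                       expected = exp_ct, expected_pct = exp_pct,
                       p_value = p, stringsAsFactors = FALSE)),
    class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> n=%d observed distances\n", x$n_observed))
  print(x$table, row.names = FALSE)
  invisible(x)
}
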