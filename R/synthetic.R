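# Synthetic promoter/peak/expression/sequence generator. The defaults encode
# the statistical structure the downstream analyses assume: a factor with a
# bimodal TSS-relative offset law (modes -250/+650 bp) and per-promoter peak
# multiplicity, co-occurring with a TSS-centered factor, expression coupled
# to the co-binding class, and genome sequence in which TAATCC-family motifs
# are depleted near the TSS, E-boxes enriched at it, and soft-masked
# Alu-like repeats are rich in TAATCC.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic promoter-binding generator
#'
#' Fractions default to the study conditions of the emulated experiment:
#' 45.4% of promoters bound by the bimodal factor ("OTX2"), 40.2% of bound
#' promoters carrying two or more peaks, MYC co-binding probabilities 0.638
#' given multiple and 0.487 given single OTX2 binding, and an overall MYC
#' marginal of 0.515 from which the MYC rate on OTX2-free promoters is
#' solved by the law of total probability.
#'
#' @param n_promoters number of promoter regions.
#' @param seed master RNG seed; component sub-seeds are derived from it.
#' @param p_otx2_bound probability a promoter carries >=1 OTX2 peak.
#' @param p_multi_given_bound probability a bound promoter has >=2 peaks.
#' @param otx2_offset_law `"mixture"` (the bimodal default) or `"uniform"`,
#'   which draws OTX2 offsets uniformly over the +/-2000 bp binding window —
#'   the exact law assumed by the distance randomization null, used for
#'   calibration runs.
#' @param otx2_offset_means,otx2_offset_sds,otx2_offset_weights two-component
#'   Gaussian mixture for OTX2 peak offsets (bp, strand-aware).
#' @param myc_offset_mean,myc_offset_sd TSS-centered Gaussian for MYC peak
#'   offsets (bp).
#' @param p_myc_given_multi,p_myc_given_single,p_myc_marginal MYC co-binding
#'   law; the rate given no OTX2 binding is solved from the marginal.
#' @param p_extra_geom geometric parameter for the number of extra peaks on
#'   multiple-bound promoters (truncated so total peaks <= `max_peaks`).
#' @param max_peaks cap on peaks per promoter.
#' @param peak_width called peak width in bp.
#' @param myc_coupling_sd if non-`NULL`, MYC offsets on co-bound promoters
#'   are drawn around the first OTX2 peak with this sd instead of around the
#'   TSS (proximity coupling switched on).
#' @param probe_spacing,noise_sd,signal_mean,signal_sd signal-track layout:
#'   probe pitch in bp, additive Gaussian probe noise, and the law of
#'   per-peak log2 amplitudes.
#' @param expression_class_means,expression_sd per-co-binding-class mean log2
#'   expression with a common sd; set all means equal to decouple expression
#'   from binding.
#' @param taatcc_rate_per_kb,depletion_halfwidth,depletion_ramp planted
#'   TAATCC-family placement: rate per kb far from the TSS, zero within
#'   `depletion_halfwidth` of the TSS, ramping linearly to the far rate over
#'   `depletion_ramp` bp.
#' @param ebox_per_promoter,ebox_sd expected planted E-boxes per promoter,
#'   placed at Gaussian offsets around the TSS.
#' @param repeat_density,repeat_length,repeat_taatcc expected soft-masked
#'   Alu-like insertions per promoter, their length, and the number of
#'   TAATCC copies planted inside each.
#' @param promoters_per_chrom,tss_spacing,first_tss chromosome layout; the
#'   default spacing keeps -5000..+3000 windows disjoint.
#' @param window promoter window (bp offsets) used for signal probes and
#'   sequence planting.
#' @param close_tss_fraction fraction of promoters given an extra same-gene
#'   TSS < 150 bp away (to exercise the TSS spacing filter); 0 by default.
#' @return A `synthetic_config` list with the solved
#'   `p_myc_given_no_otx2` added.
#' @export
synthetic_config <- function(n_promoters = 25064,
                             seed = 1,
                             p_otx2_bound = 0.454,
                             p_multi_given_bound = 0.402,
                             otx2_offset_law = c("mixture", "uniform"),
                             otx2_offset_means = c(-250, 650),
                             otx2_offset_sds = c(200, 200),
                             otx2_offset_weights = c(0.5, 0.5),
                             myc_offset_mean = 0,
                             myc_offset_sd = 150,
                             p_myc_given_multi = 0.638,
                             p_myc_given_single = 0.487,
                             p_myc_marginal = 0.515,
                             p_extra_geom = 0.5,
                             max_peaks = 5,
                             peak_width = 300,
                             myc_coupling_sd = NULL,
                             probe_spacing = 100,
                             noise_sd = 0.3,
                             signal_mean = 2,
                             signal_sd = 0.5,
                             expression_class_means = c("unbound" = 5.8,
                                                        "MYC-only" = 6.2,
                                                        "single-MYC" = 6.1,
                                                        "single+MYC" = 6.4,
                                                        "multi-MYC" = 6.3,
                                                        "multi+MYC" = 7.3),
                             expression_sd = 1,
                             taatcc_rate_per_kb = 1.2,
                             depletion_halfwidth = 500,
                             depletion_ramp = 500,
                             ebox_per_promoter = 0.6,
                             ebox_sd = 150,
                             repeat_density = 0.5,
                             repeat_length = 300,
                             repeat_taatcc = 3,
                             promoters_per_chrom = 1000,
                             tss_spacing = 10200,
                             first_tss = 6000,
                             window = c(-5000, 3000),
                             close_tss_fraction = 0) {
  cfg <- as.list(environment())
  cfg$otx2_offset_law <- match.arg(otx2_offset_law)
  probs <- c(p_otx2_bound, p_multi_given_bound, p_myc_given_multi,
             p_myc_given_single, p_myc_marginal, p_extra_geom,
             close_tss_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(otx2_offset_weights) - 1) > 1e-8)
    stop("otx2_offset_weights must sum to 1")
  p_single <- p_otx2_bound * (1 - p_multi_given_bound)
  p_multi <- p_otx2_bound * p_multi_given_bound
  p_none <- 1 - p_otx2_bound
  if (p_none == 0) {
    cfg$p_myc_given_no_otx2 <- NA_real_
  } else {
    x <- (p_myc_marginal - p_single * p_myc_given_single -
            p_multi * p_myc_given_multi) / p_none
    if (x < 0 || x > 1)
      stop("infeasible MYC marginal: solved P(MYC | no OTX2) = ",
           signif(x, 4), " lies outside [0, 1]")
    cfg$p_myc_given_no_otx2 <- x
  }
  class(cfg) <- "synthetic_config"
  cfg
}

cobind_levels <- function() {
  c("unbound", "MYC-only", "single-MYC", "single+MYC", "multi-MYC", "multi+MYC")
}

# Promoter layout shared by the generator and the fixture builder.
promoter_layout <- function(n, promoters_per_chrom, tss_spacing, first_tss) {
  chrom_idx <- (seq_len(n) - 1L) %/% promoters_per_chrom + 1L
  within <- (seq_len(n) - 1L) %% promoters_per_chrom
  data.frame(gene_id = sprintf("G%06d", seq_len(n)),
             chrom = sprintf("chrS%d", chrom_idx),
             position = as.integer(first_tss + within * tss_spacing),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic promoter-binding dataset
#'
#' Produces a TSS table, peak calls for the bimodal ("OTX2") and
#' TSS-centered ("MYC") factors, probe-level signal tracks, a gene
#' expression table, and a soft-masked genome sequence, all with the
#' statistical structure described in [synthetic_config()]. Output is
#' deterministic given the config seed; each component draws from its own
#' derived sub-seed, so e.g. peaks are identical whether or not sequence is
#' generated.
#'
#' @param config a [synthetic_config()].
#' @param what which components to materialize (sequence at large
#'   `n_promoters` is by far the most expensive).
#' @return A list with elements `config`, `tss`, `truth` (per-promoter
#'   planted class), `otx2_peaks`, `myc_peaks`, `signal` (list of tracks),
#'   `expression`, `genome`; unrequested components are `NULL`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             what = c("peaks", "signal", "expression", "sequence")) {
  stopifnot(inherits(config, "synthetic_config"))
  what <- match.arg(what, several.ok = TRUE)
  sub_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, 4L))

  core <- with_seed(sub_seeds[1], generate_core(config))
  out <- list(config = config, tss = core$tss, truth = core$truth,
              otx2_peaks = NULL, myc_peaks = NULL, signal = NULL,
              expression = NULL, genome = NULL)
  if (any(c("peaks", "signal") %in% what)) {
    out$otx2_peaks <- core$otx2_peaks
    out$myc_peaks <- core$myc_peaks
  }
  if ("signal" %in% what)
    out$signal <- with_seed(sub_seeds[2], list(
      OTX2 = simulate_track(config, core$truth, core$otx2_peaks),
      MYC = simulate_track(config, core$truth, core$myc_peaks)))
  if ("expression" %in% what)
    out$expression <- with_seed(sub_seeds[3], simulate_expression(config, core$truth))
  if ("sequence" %in% what)
    out$genome <- with_seed(sub_seeds[4], simulate_genome(config, core$truth))
  out
}

generate_core <- function(cfg) {
  n <- cfg$n_promoters
  lay <- promoter_layout(n, cfg$promoters_per_chrom, cfg$tss_spacing, cfg$first_tss)
  strand <- sample(c("+", "-"), n, replace = TRUE)

  bound <- runif(n) < cfg$p_otx2_bound
  multi <- bound & (runif(n) < cfg$p_multi_given_bound)
  extra <- pmin(rgeom(n, cfg$p_extra_geom), cfg$max_peaks - 2L)
  k <- ifelse(!bound, 0L, ifelse(multi, 2L + extra, 1L))

  p_myc <- ifelse(multi, cfg$p_myc_given_multi,
                  ifelse(bound, cfg$p_myc_given_single, cfg$p_myc_given_no_otx2))
  myc <- runif(n) < p_myc

  cls <- ifelse(!bound & !myc, "unbound",
                ifelse(!bound, "MYC-only",
                       ifelse(multi, ifelse(myc, "multi+MYC", "multi-MYC"),
                              ifelse(myc, "single+MYC", "single-MYC"))))

  # OTX2 peak offsets: two-component mixture, or uniform over the binding
  # window (the law the randomization null assumes, for calibration runs)
  total_k <- sum(k)
  if (cfg$otx2_offset_law == "uniform") {
    otx2_off <- as.integer(round(runif(total_k, -2000, 2000)))
  } else {
    comp <- sample(seq_along(cfg$otx2_offset_weights), total_k, replace = TRUE,
                   prob = cfg$otx2_offset_weights)
    otx2_off <- as.integer(round(rnorm(total_k, cfg$otx2_offset_means[comp],
                                       cfg$otx2_offset_sds[comp])))
  }
  owner <- rep.int(seq_len(n), k)

  # MYC peak offsets: TSS-centered, or coupled to the first OTX2 peak
  myc_idx <- which(myc)
  myc_off <- as.integer(round(rnorm(length(myc_idx), cfg$myc_offset_mean,
                                    cfg$myc_offset_sd)))
  if (!is.null(cfg$myc_coupling_sd) && total_k > 0) {
    first_off <- otx2_off[match(seq_len(n), owner)]
    has_otx2 <- !is.na(first_off[myc_idx])
    coupled <- as.integer(round(first_off[myc_idx][has_otx2] +
                                  rnorm(sum(has_otx2), 0, cfg$myc_coupling_sd)))
    myc_off[has_otx2] <- coupled
  }

  tss <- tss_table(lay$gene_id, lay$chrom, lay$position, strand)

  to_center <- function(idx, off)
    as.integer(ifelse(strand[idx] == "+", lay$position[idx] + off,
                      lay$position[idx] - off))
  hw <- cfg$peak_width %/% 2L
  otx2_center <- to_center(owner, otx2_off)
  otx2_peaks <- peak_table(lay$chrom[owner], otx2_center - hw,
                           otx2_center - hw + cfg$peak_width,
                           rnorm(total_k, cfg$signal_mean, cfg$signal_sd), "OTX2")
  otx2_peaks$gene_id <- lay$gene_id[owner]
  myc_center <- to_center(myc_idx, myc_off)
  myc_peaks <- peak_table(lay$chrom[myc_idx], myc_center - hw,
                          myc_center - hw + cfg$peak_width,
                          rnorm(length(myc_idx), cfg$signal_mean, cfg$signal_sd), "MYC")
  myc_peaks$gene_id <- lay$gene_id[myc_idx]

  # optional extra same-gene TSSs closer than 150 bp, for the spacing filter
  if (cfg$close_tss_fraction > 0) {
    pick <- which(runif(n) < cfg$close_tss_fraction)
    if (length(pick)) {
      d <- sample(40:140, length(pick), replace = TRUE)
      tss <- rbind(tss, tss_table(lay$gene_id[pick], lay$chrom[pick],
                                  lay$position[pick] + d, strand[pick]))
      tss <- tss[order(tss$chrom, tss$position), ]
      rownames(tss) <- NULL
    }
  }

  truth <- data.frame(lay, strand = strand, bound = bound,
                      n_otx2_peaks = as.integer(k), myc_bound = myc,
                      cobind_class = factor(cls, levels = cobind_levels()),
                      stringsAsFactors = FALSE)
  list(tss = tss, truth = truth, otx2_peaks = otx2_peaks, myc_peaks = myc_peaks)
}

simulate_track <- function(cfg, truth, peaks) {
  offs <- seq(cfg$window[1], cfg$window[2] - 1L, by = cfg$probe_spacing)
  n <- nrow(truth)
  pos <- rep(truth$position, each = length(offs)) +
    ifelse(rep(truth$strand, each = length(offs)) == "+", 1, -1) * rep(offs, n)
  chrom <- rep(truth$chrom, each = length(offs))
  value <- rnorm(length(pos), 0, cfg$noise_sd)
  if (nrow(peaks) > 0) {
    sigma <- cfg$peak_width / 4
    pk_row <- match(peaks$gene_id, truth$gene_id)
    P <- length(offs)
    by_prom <- split(seq_len(nrow(peaks)), pk_row)
    for (pr in names(by_prom)) {
      i <- as.integer(pr)
      probes <- ((i - 1L) * P + 1L):(i * P)
      for (j in by_prom[[pr]]) {
        value[probes] <- value[probes] + peaks$signal[j] *
          exp(-(pos[probes] - peaks$center[j])^2 / (2 * sigma^2))
      }
    }
  }
  signal_track(chrom, pos, value)
}

simulate_expression <- function(cfg, truth) {
  mu <- cfg$expression_class_means[as.character(truth$cobind_class)]
  expression_table(truth$gene_id, rnorm(nrow(truth), mu, cfg$expression_sd))
}

simulate_genome <- function(cfg, truth) {
  bases <- c("A", "C", "G", "T")
  win <- cfg$window
  # TAATCC-family placement weights over the window: depleted near the TSS
  motif_offs <- win[1]:(win[2] - 6L)
  ramp <- pmin(1, pmax(0, (abs(motif_offs) - cfg$depletion_halfwidth) /
                         cfg$depletion_ramp))
  expected_taatcc <- cfg$taatcc_rate_per_kb * sum(ramp) / 1000
  fam <- c("TAATCC", "TAAGCC", "TAATCT")

  genome <- character(0)
  for (chr in unique(truth$chrom)) {
    rows <- which(truth$chrom == chr)
    L <- max(truth$position[rows]) + abs(win[1]) + win[2] + 1000L
    seqv <- sample(bases, L, replace = TRUE)
    for (i in rows) {
      pos <- truth$position[i]
      minus <- truth$strand[i] == "-"
      plant <- function(off, motif) {
        m <- if (minus) revcomp(motif) else motif
        k <- nchar(m)
        g0 <- if (minus) pos - off - (k - 1L) else pos + off
        if (g0 >= 0 && g0 + k <= L)
          seqv[(g0 + 1L):(g0 + k)] <<- strsplit(m, "")[[1]]
      }
      n_fam <- rpois(1, expected_taatcc)
      if (n_fam > 0) {
        offs <- sample(motif_offs, n_fam, replace = TRUE, prob = ramp)
        ms <- sample(fam, n_fam, replace = TRUE, prob = c(0.6, 0.2, 0.2))
        for (j in seq_len(n_fam)) plant(offs[j], ms[j])
      }
      n_ebox <- rpois(1, cfg$ebox_per_promoter)
      if (n_ebox > 0) {
        offs <- pmax(win[1], pmin(win[2] - 6L,
                                  as.integer(round(rnorm(n_ebox, 0, cfg$ebox_sd)))))
        for (j in seq_len(n_ebox)) plant(offs[j], "CACGTG")
      }
      n_rep <- rpois(1, cfg$repeat_density)
      if (n_rep > 0) {
        for (j in seq_len(n_rep)) {
          off <- sample(win[1]:(win[2] - cfg$repeat_length), 1)
          rep_seq <- sample(bases, cfg$repeat_length, replace = TRUE)
          slots <- round(seq(1, cfg$repeat_length - 5, length.out = cfg$repeat_taatcc))
          for (s in slots) rep_seq[s:(s + 5)] <- strsplit("TAATCC", "")[[1]]
          g0 <- if (minus) pos - off - (cfg$repeat_length - 1L) else pos + off
          if (g0 >= 0 && g0 + cfg$repeat_length <= L)
            seqv[(g0 + 1L):(g0 + cfg$repeat_length)] <- tolower(rep_seq)
        }
      }
    }
    genome[[chr]] <- paste(seqv, collapse = "")
  }
  validate_genome(genome)
  genome
}

#' Build a deterministic fixture with exact binding counts
#'
#' Constructs a TSS table plus peak calls in which exactly the stated
#' numbers of promoters carry one OTX2 peak, two OTX2 peaks, and MYC peaks,
#' with all peak centers within +/-2000 bp of their TSS. Used to reproduce a
#' published contingency table exactly.
#'
#' @param counts list or named vector with elements `total`, `single`,
#'   `multi`, `myc_total`, `myc_and_single`, `myc_and_multi`.
#' @param peak_width,tss_spacing,promoters_per_chrom,first_tss layout knobs.
#' @return A list with `tss`, `otx2_peaks`, `myc_peaks`.
#' @export
generate_fixture_from_counts <- function(counts, peak_width = 300,
                                         tss_spacing = 10200,
                                         promoters_per_chrom = 1000,
                                         first_tss = 6000) {
  need <- c("total", "single", "multi", "myc_total", "myc_and_single",
            "myc_and_multi")
  counts <- as.list(counts)
  if (!all(need %in% names(counts))) stop("counts must contain: ",
                                          paste(need, collapse = ", "))
  ct <- lapply(counts[need], as.integer)
  with(ct, {
    if (any(unlist(ct) < 0)) stop("inconsistent counts: negative entry")
    if (single + multi > total) stop("inconsistent counts: single + multi > total")
    if (myc_and_single > single) stop("inconsistent counts: myc_and_single > single")
    if (myc_and_multi > multi) stop("inconsistent counts: myc_and_multi > multi")
    if (myc_and_single + myc_and_multi > myc_total)
      stop("inconsistent counts: joint cells exceed myc_total")
    if (myc_total - myc_and_single - myc_and_multi > total - single - multi)
      stop("inconsistent counts: MYC-only exceeds OTX2-free promoters")
  })
  lay <- promoter_layout(ct$total, promoters_per_chrom, tss_spacing, first_tss)
  tss <- tss_table(lay$gene_id, lay$chrom, lay$position, "+")

  is_multi <- seq_len(ct$total) <= ct$multi
  is_single <- seq_len(ct$total) > ct$multi & seq_len(ct$total) <= ct$multi + ct$single
  myc <- logical(ct$total)
  myc[seq_len(ct$myc_and_multi)] <- TRUE
  myc[ct$multi + seq_len(ct$myc_and_single)] <- TRUE
  n_myc_only <- ct$myc_total - ct$myc_and_single - ct$myc_and_multi
  if (n_myc_only > 0)
    myc[ct$multi + ct$single + seq_len(n_myc_only)] <- TRUE

  hw <- peak_width %/% 2L
  mk_peaks <- function(idx, off, label) {
    ctr <- lay$position[idx] + off
    pk <- peak_table(lay$chrom[idx], ctr - hw, ctr - hw + peak_width, 2, label)
    pk$gene_id <- lay$gene_id[idx]
    pk
  }
  otx2 <- rbind(mk_peaks(which(is_multi | is_single), -250L, "OTX2"),
                mk_peaks(which(is_multi), 650L, "OTX2"))
  otx2 <- otx2[order(otx2$chrom, otx2$start), ]
  rownames(otx2) <- NULL
  list(tss = tss, otx2_peaks = otx2,
       myc_peaks = mk_peaks(which(myc), 0L, "MYC"))
}
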