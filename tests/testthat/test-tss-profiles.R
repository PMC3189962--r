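test_that("TSS spacing filter keeps the first of each close run, per gene", {
  tss <- make_tss(c(0, 100, 400), gene = rep("g1", 3))
  expect_equal(filter_tss(tss)$position, c(0L, 400L))
  # spacing of exactly 150 is kept
  expect_equal(filter_tss(make_tss(c(0, 150), gene = rep("g1", 2)))$position,
               c(0L, 150L))
  expect_equal(nrow(filter_tss(make_tss(5000))), 1L)
  # promoters of different genes are never compared
  two <- make_tss(c(0, 50), gene = c("g1", "g2"))
  expect_equal(nrow(filter_tss(two)), 2L)
  # chained rule: distance is to the previously *retained* TSS
  tss <- make_tss(c(0, 100, 200, 360), gene = rep("g1", 4))
  expect_equal(filter_tss(tss)$position, c(0L, 200L, 360L))
  expect_equal(nrow(filter_tss(make_tss(5000)[0, ])), 0L)
})

test_that("mean signal binning follows the half-open bin convention", {
  tss <- make_tss(10000)
  trk <- signal_track("chr1", c(9740, 9760), c(2, 4))
  prof <- mean_signal_profile(trk, tss, window = c(-500, 500))
  expect_equal(prof$values[prof$centers == -275], 2)  # offset -260 in [-300,-250)
  expect_equal(prof$values[prof$centers == -225], 4)  # offset -240 in [-250,-200)
  expect_true(all(is.na(prof$values[!prof$centers %in% c(-275, -225)])))

  # constant track is constant on every informative bin, no edge effects
  tss3 <- make_tss(c(10000, 30000, 50000))
  trk <- signal_track("chr1", seq(3000, 57000, by = 37), 1.0)
  prof <- mean_signal_profile(trk, tss3, window = c(-5000, 3000))
  expect_true(all(prof$values[!is.na(prof$values)] == 1.0))
  expect_gt(sum(!is.na(prof$values)), 100)
})

test_that("mean signal pooling matches a brute-force double loop", {
  withr::local_seed(11)
  for (rep in 1:3) {
    tss <- make_tss(sort(sample(5000:50000, 6)),
                    strand = sample(c("+", "-"), 6, TRUE))
    trk <- signal_track("chr1", sort(sample.int(60000, 300)), rnorm(300))
    win <- c(-1000, 500)
    prof <- mean_signal_profile(trk, tss, window = win, bin_width = 50)
    nb <- diff(win) / 50
    acc <- vector("list", nb)
    for (i in seq_len(nrow(tss))) for (j in seq_len(nrow(trk))) {
      off <- offset_oracle(trk$position[j], tss$position[i], tss$strand[i])
      if (off >= win[1] && off < win[2]) {
        b <- (off - win[1]) %/% 50 + 1
        acc[[b]] <- c(acc[[b]], trk$value[j])
      }
    }
    expected <- vapply(acc, function(x) if (is.null(x)) NA_real_ else mean(x), 0)
    expect_equal(prof$values, expected)
    expect_equal(prof$n_informative, vapply(acc, length, 0L))
  }
})

test_that("peak frequency counts promoters once per bin", {
  tss <- make_tss(c(10000, 20000, 30000, 40000))
  pk <- peak_table("chr1", 10000 - 260 - 150, 10000 - 260 + 150)  # offset -260
  prof <- peak_frequency_profile(pk, tss, window = c(-500, 500))
  expect_equal(prof$values[prof$centers == -275], 25)
  expect_equal(sum(prof$values), 25)

  # two peaks of one promoter in the same bin count once
  pk2 <- peak_table("chr1", c(9720, 9740), c(10020, 10040))  # centers 9870, 9890
  prof <- peak_frequency_profile(pk2, tss, window = c(-500, 500))
  expect_equal(prof$values[prof$centers == -125], 25)
})

test_that("peak-bin assignment conserves counts against a double loop", {
  withr::local_seed(23)
  for (rep in 1:4) {
    n <- sample(10:50, 1)
    tss <- make_tss(sort(sample(seq(5000, 2e5, by = 10), n)),
                    strand = sample(c("+", "-"), n, TRUE))
    ctr <- sample.int(2e5, 80)
    pk <- peak_table("chr1", ctr - 100, ctr + 100)
    win <- c(-2000, 2000)
    prof <- peak_frequency_profile(pk, tss, window = win, bin_width = 50)
    hit <- matrix(FALSE, n, diff(win) / 50)
    for (i in seq_len(n)) for (j in seq_len(nrow(pk))) {
      off <- offset_oracle(pk$center[j], tss$position[i], tss$strand[i])
      if (off >= win[1] && off < win[2]) hit[i, (off - win[1]) %/% 50 + 1] <- TRUE
    }
    expect_equal(prof$n_informative, unname(colSums(hit)))
    expect_equal(prof$values, unname(100 * colSums(hit) / n))
  }
})

test_that("profiles are invariant under coordinate mirroring with strand flip", {
  withr::local_seed(31)
  n <- 20
  tss <- make_tss(sort(sample(10000:90000, n)), strand = sample(c("+", "-"), n, TRUE))
  ctr <- sample(5000:95000, 60)
  pk <- peak_table("chr1", ctr - 150, ctr + 150)
  trk <- signal_track("chr1", sort(sample(5000:95000, 400)), rnorm(400))
  M <- 100000L
  mirror_strand <- ifelse(tss$strand == "+", "-", "+")
  tss_m <- tss_table(tss$gene_id, tss$chrom, M - tss$position, mirror_strand)
  pk_m <- peak_table("chr1", M - pk$center, M - pk$center + 300)
  pk_m$center <- M - pk$center  # mirrored centers exactly
  trk_m <- signal_track("chr1", M - trk$position, trk$value)

  pf <- peak_frequency_profile(pk, tss, window = c(-2000, 2000))
  pf_m <- peak_frequency_profile(pk_m, tss_m, window = c(-2000, 2000))
  expect_equal(pf$values, pf_m$values)

  sf <- mean_signal_profile(trk, tss, window = c(-2000, 2000))
  sf_m <- mean_signal_profile(trk_m, tss_m, window = c(-2000, 2000))
  expect_equal(sf$values, sf_m$values)
})

test_that("mode detection finds strict prominent maxima with TSS-ward ties", {
  mk_prof <- function(values, bin_width = 50, lower = -150) {
    structure(list(kind = "percent_bound",
                   window = c(lower, lower + bin_width * length(values)),
                   bin_width = bin_width,
                   centers = lower + bin_width * (seq_along(values) - 1) +
                     bin_width / 2,
                   values = values, n_informative = rep(1L, length(values)),
                   n_promoters = 1L),
              class = "binned_profile")
  }
  m <- find_profile_modes(mk_prof(c(0, 1, 0, 0, 2, 0)))
  expect_equal(m$offset, c(-75, 75))
  expect_equal(m$value, c(1, 2))

  # monotone increasing: single boundary mode at the last bin
  m <- find_profile_modes(mk_prof(c(1, 2, 3, 4, 5, 6)))
  expect_equal(m$offset, 125)

  # plateau resolves to the bin nearest the TSS
  m <- find_profile_modes(mk_prof(c(0, 3, 3, 3, 0, 0)))
  expect_equal(m$offset, -25)

  # prominence threshold suppresses minor wiggles
  m <- find_profile_modes(mk_prof(c(0, 10, 9.8, 10.1, 0, 0)),
                          min_prominence = 1)
  expect_equal(nrow(m), 1L)
  expect_equal(m$offset, 25)  # the higher of the twin summits

  expect_error(find_profile_modes(mk_prof(c(NA_real_, NA_real_, NA_real_))),
               "no informative")
})

test_that("promoter matrix applies the strict informative-bin filter and stable sort", {
  # probes in exactly 100 vs 101 distinct bins of the -5000..3000 window
  mk_probes <- function(tss_pos, nbins) {
    offs <- seq(-5000, by = 50, length.out = nbins)
    signal_track("chr1", tss_pos + offs + 10, 1.0)
  }
  tss <- make_tss(c(100000, 300000), gene = c("a", "b"))
  trk <- signal_track(
    "chr1",
    c(mk_probes(100000, 100)$position, mk_probes(300000, 101)$position),
    1.0)
  mat <- promoter_matrix(trk, tss, sort_key = c(1, 2))
  expect_equal(rownames(mat), "b")  # 100 informative bins is excluded

  # equal keys preserve input order; higher keys sort first
  tss3 <- make_tss(c(100000, 300000, 500000), gene = c("a", "b", "c"))
  trk3 <- signal_track("chr1", rep(tss3$position, each = 102) +
                         seq(-5000, by = 50, length.out = 102), 1.0)
  mat <- promoter_matrix(trk3, tss3, sort_key = c(1, 2, 2))
  expect_equal(rownames(mat), c("b", "c", "a"))
  expect_message(promoter_matrix(trk3, tss3, sort_key = c(1, NA, 2)),
                 "missing sort key")
})
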