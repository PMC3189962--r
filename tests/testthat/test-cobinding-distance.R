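test_that("observed distances use the nearest MYC center on single-OTX2 promoters", {
  tss <- make_tss(c(10000, 30000), gene = c("a", "b"))
  otx2 <- peak_table("chr1", c(11000, 30000) - 150, c(11000, 30000) + 150,
                     factor_label = "OTX2")
  myc <- peak_table("chr1", c(10900, 11500, 30000) - 150,
                    c(10900, 11500, 30000) + 150, factor_label = "MYC")
  cl <- classify_from(tss, otx2, myc)
  d <- observed_distances(cl$summaries, cl$otx2_assign, cl$myc_assign, otx2, myc)
  expect_equal(unname(d), c(100L, 0L))  # nearest of {100, 500}; co-located
  expect_equal(names(d), c("a", "b"))

  # inconsistent flag is an error
  bad <- cl$summaries
  bad$cobind_class[2] <- "single+MYC"
  bad$n_otx2_peaks[2] <- 1L
  ma2 <- cl$myc_assign[cl$myc_assign$tss_idx != 2, ]
  expect_error(observed_distances(bad, cl$otx2_assign, ma2, otx2, myc),
               "no assigned MYC peak")
})

test_that("observed distances match an exhaustive pairwise-minimum oracle", {
  withr::local_seed(41)
  ds <- generate_dataset(synthetic_config(n_promoters = 400, seed = 41),
                         what = "peaks")
  cl <- classify_from(ds$tss, ds$otx2_peaks, ds$myc_peaks)
  d <- observed_distances(cl$summaries, cl$otx2_assign, cl$myc_assign,
                          ds$otx2_peaks, ds$myc_peaks)
  idx <- which(cl$summaries$cobind_class == "single+MYC")
  expect_gt(length(idx), 20)
  for (j in seq_along(idx)) {
    i <- idx[j]
    oc <- ds$otx2_peaks$center[cl$otx2_assign$peak_idx[cl$otx2_assign$tss_idx == i]]
    mc <- ds$myc_peaks$center[cl$myc_assign$peak_idx[cl$myc_assign$tss_idx == i]]
    expect_equal(unname(d[j]), min(abs(outer(oc, mc, "-"))))
  }
})

test_that("the randomization null is deterministic and follows the uniform folding law", {
  # MYC fixed at the TSS: null distances are |U|, U ~ Uniform(-2000, 2000)
  n <- 10000
  tss <- make_tss(seq(10000, by = 10000, length.out = n),
                  gene = sprintf("g%d", 1:n))
  otx2 <- peak_table("chr1", tss$position + 500 - 150, tss$position + 500 + 150,
                     factor_label = "OTX2")
  myc <- peak_table("chr1", tss$position - 150, tss$position + 150,
                    factor_label = "MYC")
  cl <- classify_from(tss, otx2, myc)
  n1 <- randomized_null(cl$summaries, cl$otx2_assign, cl$myc_assign,
                        otx2, myc, R = 1, seed = 99)
  n2 <- randomized_null(cl$summaries, cl$otx2_assign, cl$myc_assign,
                        otx2, myc, R = 1, seed = 99)
  expect_identical(n1, n2)
  d <- n1$pooled
  expect_equal(length(d), n)
  # |U| is Uniform(0, 2000): check mean and quartiles within sampling error
  expect_lt(abs(mean(d) - 1000), 3 * (2000 / sqrt(12)) / sqrt(n))
  expect_lt(abs(mean(d < 500) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(mean(d < 1500) - 0.75), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("two-sided Fisher agrees with exhaustive table enumeration", {
  expect_equal(fisher_two_sided_oracle(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  expect_equal(fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value, 34 / 70,
               tolerance = 1e-9)
  withr::local_seed(53)
  for (rep in 1:25) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher.test(tab)$p.value, fisher_two_sided_oracle(tab),
                 tolerance = 1e-9)
  }
})

test_that("range enrichment recovers no signal when observed equals the null", {
  obs <- c(50L, 150L, 350L, 700L, 1200L, 1900L)
  res <- range_enrichment(obs, obs)
  expect_true(all(res$table$p_value == 1))
  expect_equal(sum(res$table$observed_pct), 100)
  expect_error(range_enrichment(obs, obs, breaks = numeric(0)), "empty range")
  expect_error(range_enrichment(integer(0), obs), "non-empty")
})

test_that("expected percentages are stable in the number of randomizations", {
  ds <- generate_dataset(synthetic_config(n_promoters = 2000, seed = 61),
                         what = "peaks")
  cl <- classify_from(ds$tss, ds$otx2_peaks, ds$myc_peaks)
  obs <- observed_distances(cl$summaries, cl$otx2_assign, cl$myc_assign,
                            ds$otx2_peaks, ds$myc_peaks)
  nl3 <- randomized_null(cl$summaries, cl$otx2_assign, cl$myc_assign,
                         ds$otx2_peaks, ds$myc_peaks, R = 3, seed = 1)
  nl30 <- randomized_null(cl$summaries, cl$otx2_assign, cl$myc_assign,
                          ds$otx2_peaks, ds$myc_peaks, R = 30, seed = 2)
  e3 <- range_enrichment(obs, nl3)$table$expected_pct
  e30 <- range_enrichment(obs, nl30)$table$expected_pct
  # Monte-Carlo error of a percentage on ~250 x R draws
  expect_lt(max(abs(e3 - e30)), 5 * sqrt(40 * 60 / (length(obs) * 3)))
})
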