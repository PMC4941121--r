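test_that("DHS intervals are classified into the expected 2x2 cells", {
  dhs <- peak_set(data.frame(chrom = "chr1",
                             start = c(0, 1000, 2000, 3000),
                             end = c(100, 1100, 2100, 3100)), label = "dhs")
  feature <- peak_set(data.frame(chrom = "chr1", start = c(50, 1050),
                                 end = c(80, 1080)))
  snps <- variant_table(data.frame(rsid = c("s1", "s2"), chrom = "chr1",
                                   pos = c(10, 2050)))
  ct <- build_dhs_contingency(feature, snps, dhs)
  expect_equal(unlist(ct), c(a = 1, b = 1, c = 1, d = 1))

  ct0 <- build_dhs_contingency(feature, snps[0, ], dhs)
  expect_equal(ct0$a + ct0$b, 0)
  expect_equal(ct0$a + ct0$b + ct0$c + ct0$d, 4)

  expect_error(build_dhs_contingency(feature, snps, peak_set(dhs$intervals[0, ])),
               "background")
})

test_that("DHS classification matches a per-interval brute-force loop", {
  dhs_df <- random_intervals(50, 91L, max_pos = 5000, max_len = 150,
                             chroms = "chr1")
  feat_df <- random_intervals(20, 92L, max_pos = 5000, max_len = 150,
                              chroms = "chr1")
  snps <- withr::with_seed(93L, data.frame(
    rsid = paste0("s", 1:30), chrom = "chr1",
    pos = sample.int(5200, 30) - 1L))
  dhs <- ps_merge(peak_set(dhs_df))    # universe intervals non-overlapping
  feature <- peak_set(feat_df)
  ct <- build_dhs_contingency(feature, variant_table(snps), dhs)

  cells <- c(a = 0, b = 0, c = 0, d = 0)
  for (i in seq_len(nrow(dhs$intervals))) {
    di <- dhs$intervals[i, ]
    f <- any(feat_df$start < di$end & feat_df$end > di$start)
    s <- any(snps$pos >= di$start & snps$pos < di$end)
    cell <- if (f && s) "a" else if (!f && s) "b" else if (f) "c" else "d"
    cells[cell] <- cells[cell] + 1
  }
  expect_equal(unlist(ct), cells)
  expect_equal(sum(unlist(ct)), nrow(dhs$intervals))
})

test_that("Fisher's exact test reproduces trivial and enumerated outcomes", {
  sym <- fisher_exact(contingency_table(5, 5, 5, 5), "two_sided")
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)

  t2 <- contingency_table(8, 2, 1, 5)
  expect_equal(fisher_exact(t2, "two_sided")$p_value,
               enum_fisher_two_sided(8, 2, 1, 5), tolerance = 1e-12)
  expect_equal(fisher_exact(t2, "greater")$p_value,
               enum_fisher_greater(8, 2, 1, 5), tolerance = 1e-12)
})

test_that("Fisher p-values agree with stats::fisher.test across random tables", {
  withr::with_seed(71L, {
    for (i in 1:25) {
      cells <- rpois(4, sample(c(3, 10, 40), 1)) + c(1, 0, 0, 0)
      if (sum(cells) == 0) next
      ct <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
      expect_equal(fisher_exact(ct, "two_sided")$p_value,
                   stats::fisher.test(m)$p.value, tolerance = 1e-9)
      expect_equal(fisher_exact(ct, "greater")$p_value,
                   stats::fisher.test(m, alternative = "greater")$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("one-sided Fisher p is monotone decreasing in cell a at fixed margins", {
  # margins: feature+ = 20, feature- = 30, condition+ = 15
  ps <- vapply(5:15, function(a) {
    fisher_exact(contingency_table(a, 15 - a, 20 - a, 30 - (15 - a)),
                 "greater")$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate margins yield p = 1 with an undefined odds ratio", {
  r <- fisher_exact(contingency_table(0, 0, 3, 4))
  expect_equal(r$p_value, 1)
  expect_true(r$or_undefined)
})

test_that("odds-ratio confidence interval brackets the estimate", {
  r <- fisher_exact(contingency_table(30, 10, 20, 25))
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_equal(r$odds_ratio, (30 * 25) / (10 * 20))
})

test_that("binomial enrichment equals direct mass summation", {
  expect_equal(binomial_enrichment(0, 10, 0.1)$p_value, 1)
  # frozen from the independent summation oracle at n=10, p=0.1, x=3
  expect_equal(binomial_enrichment(3, 10, 0.1)$p_value, 0.0701908264,
               tolerance = 1e-8)
  for (case in list(c(3, 10, 0.1), c(1, 137, 0.004), c(480, 1000, 0.5),
                    c(40, 10000, 0.003), c(9990, 10000, 0.999))) {
    got <- binomial_enrichment(case[1], case[2], case[3])$p_value
    want <- naive_binom_tail(case[1], case[2], case[3])
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(binomial_enrichment(1, 10, 0), "strictly")
  expect_error(binomial_enrichment(11, 10, 0.1), "x must")
})

test_that("binomial p for the genome-fraction parameterization is the stated fraction", {
  # open chromatin covering 1% of the uniquely mappable genome, one SNP
  r <- binomial_enrichment(1, 1, open_bp = 26303014)
  expect_equal(r$p_value, 0.01, tolerance = 1e-6)
  expect_equal(r$fold_enrichment, 2630301437 / 26303014)
})

test_that("density profile concentrates mass at centers and conserves counts", {
  centers <- peak_set(data.frame(chrom = "chr1",
                                 start = c(1000, 5000, 9000),
                                 end = c(1200, 5200, 9200)))
  mids <- ps_midpoints(centers)
  prof <- density_profile(mids, centers, window_bp = 1000, bin_bp = 100)
  expect_length(prof$counts, 20L)
  expect_equal(sum(prof$counts), 3L)
  # offset 0 falls in the first bin right of center
  expect_equal(prof$counts[11], 3L)
  expect_equal(prof$normalized, prof$counts / 3)
  expect_error(density_profile(mids, centers, window_bp = 1000, bin_bp = 300),
               "divisible")
})

test_that("uniformly placed features give a flat profile within sampling noise", {
  withr::with_seed(55L, {
    centers <- peak_set(data.frame(chrom = "chr1",
                                   start = seq(5000, 995000, by = 10000),
                                   end = seq(5000, 995000, by = 10000) + 1))
    feats <- data.frame(chrom = "chr1", start = sample.int(1e6, 4000) - 1L)
    feats$end <- feats$start + 1
  })
  prof <- density_profile(peak_set(feats), centers)
  # chi-square goodness of fit against a uniform 20-bin profile
  chi <- sum((prof$counts - mean(prof$counts))^2 / mean(prof$counts))
  expect_gt(stats::pchisq(chi, df = 19, lower.tail = FALSE), 0.001)
})

test_that("features are assigned to their nearest center, ties leftward", {
  centers <- peak_set(data.frame(chrom = "chr1", start = c(1000, 2000),
                                 end = c(1001, 2001)))
  # feature at 1500 is equidistant; it must count for the left center (+500)
  feat <- peak_set(data.frame(chrom = "chr1", start = 1500, end = 1501))
  prof <- density_profile(feat, centers, window_bp = 1000, bin_bp = 100)
  expect_equal(prof$counts[16], 1L)  # offset +500 -> bin [500,600)
  expect_equal(sum(prof$counts), 1L)
})
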