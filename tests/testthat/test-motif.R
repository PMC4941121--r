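test_that("PWM scoring reproduces closed-form single cases", {
  # uniform matrix, uniform background: every word scores 0 (pseudocount
  # renormalization keeps columns at exactly 0.25)
  uni <- pwm(matrix(0.25, 4, 5))
  expect_equal(score_pwm("ACGTA", uni), 0)
  # single column, p(A) = 0.5, no pseudocount: "A" scores log2(0.5/0.25) = 1
  one <- pwm(matrix(c(0.5, 0.25, 0.125, 0.125), 4, 1), pseudocount = 0)
  expect_equal(score_pwm("A", one), 1)
  expect_equal(score_pwm("N", one), -Inf)
  expect_error(score_pwm("AAA", one), "width")
})

test_that("the consensus word scores at least as high as every other W-mer", {
  for (seed in c(101L, 102L)) {
    pw <- random_pwm(4, seed)
    enum <- enumerate_wmers(pw)
    expect_equal(max(enum$scores),
                 score_pwm(pwm_consensus(pw), pw), tolerance = 1e-12)
  }
})

test_that("threshold from p-value matches exhaustive W-mer enumeration", {
  g <- 1e-3
  for (W in 4:6) {
    for (seed in c(7L, 8L)) {
      pw <- random_pwm(W, seed)
      enum <- enumerate_wmers(pw, granularity = g)
      for (pv in c(0.05, 0.01, 0.001)) {
        th <- suppressWarnings(threshold_from_pvalue(pw, pv, granularity = g))
        t_int <- round(th / g)
        # oracle: group words by score, accumulate tail probabilities from
        # the top, keep the largest score-closed set with tail <= pv; the
        # documented fallback keeps the top-scoring words when none fits
        lev <- sort(unique(enum$scores), decreasing = TRUE)
        tailp <- cumsum(vapply(lev, function(s) {
          sum(enum$probs[enum$scores == s])
        }, numeric(1)))
        admitted <- lev[tailp <= pv + 1e-12]
        cutoff <- if (length(admitted)) min(admitted) else max(enum$scores)
        expect_equal(t_int, cutoff)
        want_hits <- sort(which(enum$scores >= cutoff))
        got_hits <- sort(which(enum$scores >= t_int))
        expect_equal(got_hits, want_hits)
      }
    }
  }
})

test_that("p-value 1 admits every word; unreachable p-values warn", {
  pw <- random_pwm(4, 9L)
  g <- 1e-3
  th <- threshold_from_pvalue(pw, 1, granularity = g)
  expect_true(all(enumerate_wmers(pw, granularity = g)$scores >= round(th / g)))
  expect_warning(threshold_from_pvalue(random_pwm(2, 10L), 1e-9),
                 "unreachable")
})

test_that("a planted consensus is recovered by a both-strand scan", {
  withr::with_seed(33L, {
    bg <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  })
  pw <- ap1_pwm()
  cons <- pwm_consensus(pw)
  seqs <- c(chr1 = paste0(substr(bg, 1, 500), cons, substr(bg, 508, 1000)))
  hits <- scan_sequences(seqs, pw, pvalue = 0.001)
  expect_true(any(hits$start == 500 & hits$strand == "+"))
})

test_that("scanning is strand-symmetric", {
  withr::with_seed(34L, {
    s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  })
  pw <- random_pwm(6, 35L)
  hits <- scan_sequences(c(chr1 = s), pw, pvalue = 0.01)
  hits_rc <- scan_sequences(c(chr1 = revcomp_str(s)), pw, pvalue = 0.01)
  # mirror map: a + hit at start i (0-based) in s is a - hit at L - end in rc
  L <- nchar(s)
  mirrored <- data.frame(start = L - hits$end,
                         strand = ifelse(hits$strand == "+", "-", "+"),
                         score = hits$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  got <- hits_rc[order(hits_rc$start, hits_rc$strand),
                 c("start", "strand", "score")]
  expect_equal(got$start, mirrored$start)
  expect_equal(got$strand, mirrored$strand)
  expect_equal(got$score, mirrored$score, tolerance = 1e-12)
})

test_that("a palindromic PWM pairs every forward hit with a reverse hit", {
  pal <- ap1_pwm()  # reverse-complement symmetric by construction
  withr::with_seed(36L, {
    s <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  })
  hits <- scan_sequences(c(chr1 = s), pal, pvalue = 0.01)
  fwd <- hits[hits$strand == "+", "start"]
  rev <- hits[hits$strand == "-", "start"]
  expect_setequal(fwd, rev)
})

test_that("hit counts shrink monotonically as the scan p-value tightens", {
  withr::with_seed(37L, {
    s <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  })
  pw <- random_pwm(5, 38L)
  ns <- vapply(c(0.05, 0.01, 0.001),
               function(pv) nrow(scan_sequences(c(chr1 = s), pw, pv)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("column permutation preserves composition and is seeded", {
  pw <- random_pwm(5, 50L)
  r1 <- randomize_pwm(pw, 42)
  r2 <- randomize_pwm(pw, 42)
  r3 <- randomize_pwm(pw, 43)
  expect_equal(attr(r1, "permutation"), attr(r2, "permutation"))
  expect_false(identical(attr(r1, "permutation"), seq_len(5)))
  # column multiset identical: sorted columns match
  sort_cols <- function(p) p$prob[, do.call(order, as.data.frame(t(p$prob)))]
  expect_equal(sort_cols(r1), sort_cols(pw))
  # per-base total composition exactly preserved
  expect_equal(rowSums(r1$prob), rowSums(pw$prob))
  expect_true(all(attr(r3, "permutation") %in% seq_len(5)))
  expect_error(randomize_pwm(random_pwm(1, 1L), 1), "width >= 2")
})

test_that("a permutation-invariant matrix is returned unchanged", {
  same <- pwm(matrix(rep(c(0.7, 0.1, 0.1, 0.1), 4), nrow = 4), name = "flat")
  out <- randomize_pwm(same, 7)
  expect_equal(out$prob, same$prob)
})

test_that("permutations are drawn uniformly from non-identity permutations", {
  pw <- random_pwm(3, 60L)
  draws <- vapply(1:1500, function(s) {
    paste(attr(randomize_pwm(pw, s), "permutation"), collapse = "")
  }, character(1))
  tab <- table(draws)
  expect_length(tab, 5L)            # 3! - 1 non-identity permutations
  expect_false("123" %in% names(tab))
  chi <- sum((tab - 300)^2 / 300)
  expect_gt(stats::pchisq(chi, df = 4, lower.tail = FALSE), 0.001)
})

test_that("SNP-motif distance bookkeeping fills the near and far cells", {
  snps <- variant_table(data.frame(rsid = "s", chrom = "chr1", pos = 500))
  hit <- function(center) {
    data.frame(chrom = "chr1", start = center - 3, end = center + 4,
               strand = "+", score = 10)
  }
  hits_real <- rbind(hit(550), hit(1450))
  hits_rand <- hit(550)
  out <- snp_motif_contingency(snps, hits_real, hits_rand)
  expect_equal(unlist(out$table), c(a = 1, b = 1, c = 1, d = 0))
})

test_that("an empty randomized hit set takes the degenerate Fisher path", {
  snps <- variant_table(data.frame(rsid = "s", chrom = "chr1", pos = 500))
  hits_real <- data.frame(chrom = "chr1", start = 547, end = 554,
                          strand = "+", score = 10)
  none <- hits_real[0, ]
  out <- snp_motif_contingency(snps, hits_real, none)
  expect_equal(out$table$b + out$table$d, 0)
  expect_equal(out$result$p_value, 1)
})

test_that("JASPAR-format matrices round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0000.0 test",
               "A [ 10  0  5 ]",
               "C [  0 20  5 ]",
               "G [  5  0  5 ]",
               "T [  5  0  5 ]"), path)
  mats <- read_jaspar(path)
  expect_named(mats, "MA0000.0")
  expect_equal(mats[[1]]$width, 3L)
  expect_equal(mats[[1]]$prob[, 2], c(A = 0, C = 1, G = 0, T = 0))
  ex <- system.file("extdata", "ap1_synthetic.pfm", package = "regprior")
  ap1 <- read_jaspar(ex)[[1]]
  expect_equal(pwm_consensus(ap1), "TGACTCA")
})
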