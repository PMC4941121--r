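# Independent brute-force oracles used across the test files. These stay
# deliberately naive (per-base bitmaps, all-pairs loops, full enumeration)
# so they share no code path with the implementation they check.

random_intervals <- function(n, seed, max_pos = 1000, max_len = 120,
                             chroms = c("chr1", "chr2")) {
  withr::with_seed(seed, {
    start <- sample.int(max_pos, n, replace = TRUE) - 1L
    len <- sample.int(max_len, n, replace = TRUE)
    data.frame(chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len,
               score = round(runif(n, 1, 50), 2),
               stringsAsFactors = FALSE)
  })
}

# all-pairs overlap in bp between two half-open intervals
pair_overlap_bp <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}

brute_intersect_idx <- function(a, b, min_ov = 1) {
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          pair_overlap_bp(a$start[i], a$end[i],
                          b$start[j], b$end[j]) >= min_ov) {
        hit[i] <- TRUE
        break
      }
    }
  }
  which(hit)
}

brute_covered_bp <- function(df) {
  total <- 0L
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, ]
    bases <- logical(max(sub$end))
    for (i in seq_len(nrow(sub))) {
      bases[(sub$start[i] + 1):sub$end[i]] <- TRUE
    }
    total <- total + sum(bases)
  }
  total
}

# exhaustive two-sided Fisher p over all outcomes at fixed margins, from
# binomial coefficients only
enum_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  pr <- vapply(lo:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
  }, numeric(1))
  obs <- pr[a - lo + 1]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

enum_fisher_greater <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  hi <- min(k, m)
  if (a > hi) return(0)
  sum(vapply(a:hi, function(x) {
    exp(lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k))
  }, numeric(1)))
}

# naive upper binomial tail from log factorials
naive_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  sum(vapply(x:n, function(k) {
    exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p))
  }, numeric(1)))
}

# all W-mers of a PWM with exact scores and background probabilities; with
# a granularity, scores are integer sums over the discretized matrix (the
# scoring model shared by the threshold DP and the scanner)
enumerate_wmers <- function(pw, granularity = NULL) {
  W <- pw$width
  grid <- expand.grid(rep(list(1:4), W))
  smat <- pw$score_matrix
  if (!is.null(granularity)) smat <- round(smat / granularity)
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    codes <- as.integer(grid[i, ])
    scores[i] <- sum(smat[cbind(codes, seq_len(W))])
    probs[i] <- prod(pw$background[codes])
  }
  list(scores = scores, probs = probs)
}

random_pwm <- function(W, seed, pseudocount = 0.01) {
  withr::with_seed(seed, {
    m <- matrix(runif(4 * W, 0.05, 1), nrow = 4)
  })
  pwm(m, name = paste0("rand_w", W), pseudocount = pseudocount)
}

revcomp_str <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

empty_motifs <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             instance = character(), stringsAsFactors = FALSE)
}

genome_background <- function(cfg) {
  gc <- cfg$gc_fraction
  c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
}
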