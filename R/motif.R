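# Position weight matrix scoring and scanning, the column-permutation
# randomized-matrix null, and the SNP-motif proximity contingency test.
#
# Scores are log2 odds against a background base composition. A score
# threshold is derived from a scan p-value by exact dynamic programming over
# discretized per-column score distributions (1e-3-bit granularity), the
# approach of standard genome-wide PWM scanners.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Accepts a 4-by-W matrix of per-column base counts or probabilities (rows
#' A, C, G, T). Columns are normalized to probabilities, then a pseudocount
#' is added and the column renormalized: `p' = (p + pc) / (1 + 4 pc)`. Scores
#' are `log2(p' / background)`.
#'
#' @param matrix numeric 4-by-W matrix; rows are A, C, G, T (row names, if
#'   present, are checked).
#' @param name motif identifier.
#' @param background length-4 base frequencies (A, C, G, T) summing to 1.
#' @param pseudocount small positive value added to probability columns
#'   (default 0.01).
#' @return object of class `PWM` with elements `name`, `prob` (normalized,
#'   pre-pseudocount), `score_matrix` (log2 odds), `background`,
#'   `pseudocount`, `width`.
#' @export
pwm <- function(matrix, name = "motif", background = rep(0.25, 4),
                pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM matrix must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(matrix)) &&
      !identical(toupper(rownames(matrix)), BASES)) {
    stop("PWM row names must be A, C, G, T")
  }
  if (ncol(matrix) < 1L) stop("PWM must have at least one column")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  if (any(colSums(matrix) <= 0)) stop("every PWM column needs positive mass")
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-6,
            all(background > 0), pseudocount >= 0)
  prob <- sweep(matrix, 2, colSums(matrix), "/")
  adj <- (prob + pseudocount) / (1 + 4 * pseudocount)
  smat <- log2(adj / background)
  dimnames(prob) <- dimnames(smat) <- list(BASES, NULL)
  structure(list(name = name, prob = prob, score_matrix = smat,
                 background = background, pseudocount = pseudocount,
                 width = ncol(matrix)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, pseudocount %g, consensus %s\n",
              x$name, x$width, x$pseudocount, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#'
#' The per-column most probable base (ties to the first of A, C, G, T).
#'
#' @param x a [pwm()].
#' @return character string of length W.
#' @export
pwm_consensus <- function(x) {
  paste(BASES[apply(x$prob, 2, which.max)], collapse = "")
}

#' Read JASPAR-style PFM files
#'
#' Parses the JASPAR text format: a `>identifier name` header followed by
#' four rows `A [ 12 3 0 ... ]` (brackets optional) of per-column counts.
#'
#' @param path file with one or more matrices.
#' @param background,pseudocount passed to [pwm()].
#' @return a list of [pwm()] objects, named by identifier.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' headers found in ", path)
  out <- list()
  for (i in seq_along(headers)) {
    from <- headers[i] + 1L
    to <- if (i < length(headers)) headers[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L) stop("matrix block under header ", lines[headers[i]],
                                 " has fewer than 4 rows")
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGTacgt]", "", l)
      v <- strsplit(gsub("[][]", " ", l), "\\s+")[[1]]
      as.numeric(v[nzchar(v)])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("ragged matrix rows under ", lines[headers[i]])
    mat <- do.call(rbind, rows)
    id <- sub("^>\\s*", "", lines[headers[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    out[[id]] <- pwm(mat, name = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

#' A synthetic AP-1-like PWM
#'
#' A sharp 7-bp matrix for the canonical AP-1 (JUN/FOS) recognition word
#' TGA(C/G)TCA, constructed in code (not copied from a motif database):
#' consensus bases carry probability 0.97 (the central position splits
#' 0.485/0.485 between C and G) and off-consensus bases 0.01. The matrix is
#' reverse-complement symmetric, as the biological dimer site is.
#'
#' @param background,pseudocount passed to [pwm()].
#' @return a [pwm()] named `"AP1_synthetic"`.
#' @export
ap1_pwm <- function(background = rep(0.25, 4), pseudocount = 0.01) {
  cons <- c("T", "G", "A", NA, "T", "C", "A")  # NA marks the C/G midpoint
  mat <- matrix(0.01, nrow = 4, ncol = 7, dimnames = list(BASES, NULL))
  for (j in seq_along(cons)) {
    if (is.na(cons[j])) {
      mat["C", j] <- 0.485
      mat["G", j] <- 0.485
    } else {
      mat[cons[j], j] <- 0.97
    }
  }
  pwm(mat, name = "AP1_synthetic", background = background,
      pseudocount = pseudocount)
}

seq_to_codes <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
  v[is.na(v)] <- 5L
  v
}

#' Score a single W-mer against a PWM
#'
#' Sum over positions of the log2-odds column scores. Any non-ACGT base makes
#' the score `-Inf` (never a hit).
#'
#' @param seq character string of length exactly W over A, C, G, T.
#' @param pwm a [pwm()].
#' @return a single numeric log2-odds score.
#' @export
score_pwm <- function(seq, pwm) {
  codes <- seq_to_codes(seq)
  if (length(codes) != pwm$width) {
    stop("sequence length ", length(codes), " != PWM width ", pwm$width)
  }
  if (any(codes == 5L)) return(-Inf)
  sum(pwm$score_matrix[cbind(codes, seq_len(pwm$width))])
}

## Discretized distribution of the PWM score of a random W-mer under the
## background model: returns integer score grid (units of `granularity` bits)
## and exact probabilities, by column-wise convolution.
pwm_score_distribution <- function(pwm, granularity = 1e-3) {
  R <- round(pwm$score_matrix / granularity)
  bg <- pwm$background
  probs <- 1
  lo <- 0
  for (j in seq_len(pwm$width)) {
    rj <- R[, j]
    lo_j <- min(rj)
    new <- numeric(length(probs) + max(rj) - lo_j)
    for (b in 1:4) {
      off <- rj[b] - lo_j
      idx <- seq_along(probs) + off
      new[idx] <- new[idx] + probs * bg[b]
    }
    probs <- new
    lo <- lo + lo_j
  }
  list(score_int = lo + seq_along(probs) - 1L, prob = probs,
       granularity = granularity)
}

#' Score threshold for a target scan p-value
#'
#' Returns the smallest score `s` such that a random W-mer drawn from the
#' background composition scores `>= s` with probability at most `pvalue`,
#' computed by exact dynamic programming (column-wise convolution) over the
#' score matrix discretized at `granularity` (default 1e-3 bits). The
#' discretized matrix is the scoring model shared with [scan_sequences()] —
#' the standard device of integer-scoring genome-wide PWM scanners — so the
#' threshold and the scan agree exactly on which words are hits. If the
#' p-value is not reachable (fewer than `1/pvalue` distinct outcomes), the
#' maximum achievable score is returned with a warning.
#'
#' @param pwm a [pwm()].
#' @param pvalue target tail probability in (0, 1]; the pipeline default,
#'   following genome-wide scanner practice, is 0.001.
#' @param granularity score discretization in bits.
#' @return numeric threshold (log2-odds, a multiple of `granularity`).
#' @export
threshold_from_pvalue <- function(pwm, pvalue = 0.001, granularity = 1e-3) {
  if (!(pvalue > 0 && pvalue <= 1)) stop("pvalue must lie in (0, 1]")
  dist <- pwm_score_distribution(pwm, granularity)
  tail_p <- rev(cumsum(rev(dist$prob)))
  # threshold must be an achievable score, not an empty grid point
  ok <- which(tail_p <= pvalue + 1e-12 & dist$prob > 0)
  if (length(ok) == 0L) {
    warning("pvalue ", pvalue, " unreachable for this PWM; ",
            "returning the maximum achievable score")
    return(max(dist$score_int[dist$prob > 0]) * granularity)
  }
  dist$score_int[ok[1L]] * granularity
}

## Reverse-complement view of a score matrix: scoring the forward strand with
## it equals scoring the reverse complement of the window with the original.
revcomp_matrix <- function(smat) {
  smat[4:1, rev(seq_len(ncol(smat))), drop = FALSE]
}

## Integer scan over one strand: `rmat` holds per-column scores in units of
## the discretization granularity; a window is a hit when its integer score
## sum reaches `t_int`.
scan_one_strand <- function(codes, rmat, t_int, granularity, chrom, strand) {
  W <- ncol(rmat)
  L <- length(codes)
  if (L < W) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  rmat5 <- rbind(rmat, rep(-Inf, W))  # row 5 absorbs ambiguous bases
  n <- L - W + 1L
  total <- numeric(n)
  for (j in seq_len(W)) {
    total <- total + rmat5[cbind(codes[j:(n + j - 1L)], j)]
  }
  hit <- which(total >= t_int)
  data.frame(chrom = rep(chrom, length(hit)), start = hit - 1L,
             end = hit - 1L + W, strand = rep(strand, length(hit)),
             score = total[hit] * granularity, stringsAsFactors = FALSE)
}

#' Scan sequences for PWM matches on both strands
#'
#' Reports every position, on both strands by default, whose score reaches
#' the threshold implied by `pvalue` (or an explicit `threshold`). Scanning
#' uses the score matrix discretized at `granularity` — the same model the
#' threshold computation uses, so the two agree exactly on the hit set;
#' reported scores are therefore multiples of `granularity` (within
#' `W * granularity / 2` of the exact log2-odds score). Reverse-strand hits
#' are reported in forward coordinates over the same half-open window.
#' Output is deterministically ordered by `(chrom, start, strand)`.
#'
#' @param sequences a named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param pwm a [pwm()].
#' @param pvalue scan p-value used to derive the threshold (default 0.001).
#' @param threshold explicit score threshold; overrides `pvalue` when given.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param granularity score discretization in bits (must match the value
#'   used for the threshold).
#' @return data.frame of hits: `chrom`, `start`, `end` (0-based half-open,
#'   width W), `strand`, `score`.
#' @export
scan_sequences <- function(sequences, pwm, pvalue = 0.001, threshold = NULL,
                           strands = c("both", "+", "-"),
                           granularity = 1e-3) {
  strands <- match.arg(strands)
  seqs <- as_sequence_vector(sequences)
  if (is.null(threshold)) {
    threshold <- threshold_from_pvalue(pwm, pvalue, granularity)
  }
  t_int <- as.integer(ceiling(threshold / granularity - 1e-6))
  rmat <- round(pwm$score_matrix / granularity)
  out <- list()
  for (nm in names(seqs)) {
    codes <- seq_to_codes(seqs[[nm]])
    chrom <- normalize_chrom(nm)
    if (strands %in% c("both", "+")) {
      out[[length(out) + 1L]] <- scan_one_strand(codes, rmat, t_int,
                                                 granularity, chrom, "+")
    }
    if (strands %in% c("both", "-")) {
      out[[length(out) + 1L]] <- scan_one_strand(codes, revcomp_matrix(rmat),
                                                 t_int, granularity,
                                                 chrom, "-")
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) {
    hits <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       score = numeric(), stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$chrom, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

as_sequence_vector <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    setNames(as.character(sequences), names(sequences))
  } else if (is.character(sequences) && length(sequences) == 1L &&
             file.exists(sequences)) {
    ss <- Biostrings::readDNAStringSet(sequences)
    names(ss) <- sub("\\s.*$", "", names(ss))
    setNames(as.character(ss), names(ss))
  } else if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- paste0("chr", seq_along(sequences))
    }
    sequences
  } else {
    stop("sequences must be a character vector, DNAStringSet or FASTA path")
  }
}

#' Column-permutation randomized PWM
#'
#' The randomized-matrix null model: permutes the columns of the matrix so
#' that the overall base composition (and per-column information content) of
#' the randomized matrix is identical to the original, eliminating base
#' composition bias while destroying the positional word. The permutation is
#' drawn uniformly from non-identity permutations (for W >= 2) and is fully
#' reproducible from `seed`.
#'
#' @param x a [pwm()] with W >= 2.
#' @param seed integer seed for the permutation draw.
#' @return a [pwm()] with permuted columns; the chosen permutation is
#'   attached as attribute `"permutation"`.
#' @export
randomize_pwm <- function(x, seed) {
  W <- x$width
  if (W < 2L) stop("randomize_pwm needs a PWM of width >= 2")
  perm <- withr::with_seed(as.integer(seed), {
    repeat {
      p <- sample.int(W)
      if (any(p != seq_len(W))) break
    }
    p
  })
  out <- pwm(x$prob[, perm, drop = FALSE],
             name = paste0(x$name, "_randomized"),
             background = x$background, pseudocount = x$pseudocount)
  attr(out, "permutation") <- perm
  out
}

## Count hits whose center lies within [lo_bp, hi_bp] (absolute distance) of
## any SNP position; each hit is counted once per band, not once per SNP.
count_hits_in_band <- function(hits, snps, lo_bp, hi_bp) {
  if (nrow(hits) == 0L || nrow(snps) == 0L) return(0L)
  lev <- unique(c(hits$chrom, normalize_chrom(snps$chrom)))
  centers <- GenomicRanges::GRanges(
    seqnames = factor(hits$chrom, levels = lev),
    ranges = IRanges::IRanges(start = floor((hits$start + hits$end) / 2) + 1,
                              width = 1)
  )
  pos <- snps$pos
  chr <- normalize_chrom(snps$chrom)
  if (lo_bp == 0) {
    win_start <- pos - hi_bp
    win_end <- pos + hi_bp
    win_chr <- chr
  } else {
    win_start <- c(pos - hi_bp, pos + lo_bp)
    win_end <- c(pos - lo_bp, pos + hi_bp)
    win_chr <- c(chr, chr)
  }
  windows <- GenomicRanges::GRanges(
    seqnames = factor(win_chr, levels = lev),
    ranges = IRanges::IRanges(start = win_start + 1, end = win_end + 1)
  )
  sum(GenomicRanges::countOverlaps(centers, windows) > 0)
}

#' SNP-motif proximity contingency test
#'
#' Compares real-matrix and randomized-matrix motif hits near SNPs against a
#' distant background band: `a` = real hits within `near_bp` of any SNP,
#' `b` = randomized hits within `near_bp`, `c` = real hits at a distance in
#' `[far_lo_bp, far_hi_bp]` on either flank, `d` = randomized hits in the far
#' band. Distance is measured from SNP position to hit center, and a hit is
#' counted once per band membership (near windows of nearby SNPs may
#' overlap). Returns the table together with its one-sided Fisher result.
#'
#' @param snps a [variant_table()].
#' @param hits_real,hits_random hit data.frames from [scan_sequences()] with
#'   the true and the column-permuted matrix, on the same genome as `snps`.
#' @param near_bp half-width of the near window (default 100).
#' @param far_lo_bp,far_hi_bp distance band of the background window
#'   (defaults 900-1000).
#' @param alternative passed to [fisher_exact()].
#' @return list with elements `table` (a [contingency_table()]) and `result`
#'   (an `EnrichmentResult`).
#' @export
snp_motif_contingency <- function(snps, hits_real, hits_random,
                                  near_bp = 100, far_lo_bp = 900,
                                  far_hi_bp = 1000,
                                  alternative = "greater") {
  stopifnot(near_bp > 0, far_lo_bp > near_bp, far_hi_bp > far_lo_bp)
  tab <- contingency_table(
    a = count_hits_in_band(hits_real, snps, 0, near_bp),
    b = count_hits_in_band(hits_random, snps, 0, near_bp),
    c = count_hits_in_band(hits_real, snps, far_lo_bp, far_hi_bp),
    d = count_hits_in_band(hits_random, snps, far_lo_bp, far_hi_bp)
  )
  list(table = tab, result = fisher_exact(tab, alternative))
}
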