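# Super-enhancer stitching and rank-curve calling.
#
# Enhancer peaks on the same chromosome separated by at most the stitching
# window (12,500 bp by default, inclusive) are merged into stitched regions
# carrying the summed signal of their members; super-enhancers are the
# regions beyond the point of the min-max-normalized rank/signal curve where
# the local slope first exceeds 1 (the tangent-line rule of rank-based
# super-enhancer callers).

#' Stitch enhancer peaks into candidate super-enhancer regions
#'
#' Peaks whose gap on the same chromosome is `<= gap_bp` are merged into one
#' stitched region spanning them; its signal is the sum of member scores and
#' `member_count` records how many peaks it absorbed. Output regions are
#' pairwise separated by more than `gap_bp`.
#'
#' @param peaks a [peak_set()]; every interval must carry a signal score.
#' @param gap_bp stitching window in bp (default 12500, inclusive boundary).
#' @return data.frame of stitched regions: `chrom`, `start`, `end`,
#'   `member_count`, `signal`.
#' @export
stitch_peaks <- function(peaks, gap_bp = 12500) {
  df <- peaks$intervals
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      member_count = integer(), signal = numeric()))
  }
  if (anyNA(df$score)) {
    stop("stitch_peaks requires a signal score on every peak")
  }
  gr <- ps_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap_bp + 1)
  ov <- GenomicRanges::findOverlaps(gr, red, maxgap = gap_bp)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    member_count = as.integer(tabulate(grp, nbins = length(red))),
    signal = as.numeric(tapply(df$score, factor(grp, levels = seq_along(red)),
                               sum)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Call super-enhancers from the ranked-signal curve
#'
#' Regions are sorted by ascending signal; ranks and signals are both scaled
#' to `[0, 1]` (rank fraction, min-max signal fraction) and the local slope
#' between consecutive points is examined with a moving window of one rank
#' step. Super-enhancers are the regions strictly beyond the first point at
#' which the slope exceeds 1 — geometrically, past the point where the curve
#' rises faster than the diagonal. Calls therefore always form a suffix of
#' the signal-sorted list, and adding a constant to all signals changes
#' nothing. If all signals are equal no region is called.
#'
#' @param regions data.frame from [stitch_peaks()] (>= 3 regions).
#' @return the input with added columns `rank` (ascending signal),
#'   `signal_scaled` and logical `is_super`, sorted by rank.
#' @export
call_super_enhancers <- function(regions) {
  n <- nrow(regions)
  if (n < 3L) stop("need at least 3 stitched regions to call super-enhancers")
  ord <- order(regions$signal)
  out <- regions[ord, , drop = FALSE]
  out$rank <- seq_len(n)
  rng <- range(out$signal)
  if (diff(rng) == 0) {
    out$signal_scaled <- 0
    out$is_super <- FALSE
    rownames(out) <- NULL
    return(out)
  }
  y <- (out$signal - rng[1]) / diff(rng)
  # x step is 1/n, so slope between consecutive ranks is n * diff(y)
  slope <- n * diff(y)
  cross <- which(slope > 1)
  out$signal_scaled <- y
  out$is_super <- if (length(cross)) out$rank > cross[1L] else FALSE
  rownames(out) <- NULL
  out
}
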