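# Enrichment machinery: DHS-background contingency construction, one-sided
# Fisher's exact test, cumulative-binomial open-chromatin enrichment, and
# binned density profiles around centered features.
#
# All exact p-values are computed in log space from the base-R hypergeometric
# and binomial distribution functions, so arbitrarily large 2x2 tables do not
# overflow or underflow intermediate terms.

#' Construct a 2x2 contingency table
#'
#' Cell convention: `a` = feature+/condition+, `b` = feature-/condition+,
#' `c` = feature+/condition-, `d` = feature-/condition-. All cells must be
#' non-negative with a positive total.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return object of class `ContingencyTable`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) stop("all cells must be >= 0")
  if (sum(cells) <= 0) stop("contingency table total must be > 0")
  if (any(abs(cells - round(cells)) > 1e-8)) stop("cells must be integers")
  structure(as.list(round(cells)), class = "ContingencyTable")
}

#' @export
print.ContingencyTable <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(feature = c("+", "-"), condition = c("+", "-")))
  print(t(m))
  invisible(x)
}

new_enrichment_result <- function(odds_ratio, ci_low, ci_high, p_value,
                                  neg_log10_p, method, alternative,
                                  fold_enrichment = NA_real_,
                                  or_undefined = FALSE) {
  structure(list(odds_ratio = odds_ratio, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, neg_log10_p = neg_log10_p,
                 fold_enrichment = fold_enrichment, method = method,
                 alternative = alternative, or_undefined = or_undefined),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("%s test (%s): OR = %.4g [%.4g, %.4g], p = %.4g (-log10 p = %.2f)\n",
              x$method, x$alternative, x$odds_ratio, x$ci_low, x$ci_high,
              x$p_value, x$neg_log10_p))
  invisible(x)
}

#' Classify a DHS background into a feature-by-SNP contingency table
#'
#' Each interval of the DHS (DNaseI hypersensitivity site) background
#' universe is classified on two axes: does it overlap the feature peak set
#' by at least 1 bp, and does it contain at least one SNP of the tested set?
#' A DHS interval overlapping the feature *and* containing a SNP counts once
#' in cell `a`; the remaining cells partition the rest of the universe, so
#' the cell total always equals the number of DHS intervals. The feature set
#' is expected to be pre-filtered to DHS-overlapping intervals (see
#' [ps_intersect()]).
#'
#' @param feature a [peak_set()] (e.g. ATAC open chromatin).
#' @param snps a [variant_table()] (condition axis).
#' @param dhs_universe a [peak_set()]; must be non-empty.
#' @return a [contingency_table()].
#' @export
build_dhs_contingency <- function(feature, snps, dhs_universe) {
  if (nrow(dhs_universe$intervals) == 0L) {
    stop("dhs_universe is empty: a background is required")
  }
  check_same_genome(feature, dhs_universe)
  lev <- common_levels(feature, dhs_universe)
  dhs_gr <- ps_granges(dhs_universe, lev)
  feat_hit <- GenomicRanges::countOverlaps(dhs_gr, ps_granges(feature, lev)) > 0
  if (nrow(snps) > 0L) {
    snp_gr <- GenomicRanges::GRanges(
      seqnames = factor(normalize_chrom(snps$chrom), levels = lev),
      ranges = IRanges::IRanges(start = snps$pos + 1, width = 1)
    )
    snp_hit <- GenomicRanges::countOverlaps(dhs_gr, snp_gr) > 0
  } else {
    snp_hit <- rep(FALSE, length(dhs_gr))
  }
  contingency_table(a = sum(feat_hit & snp_hit),
                    b = sum(!feat_hit & snp_hit),
                    c = sum(feat_hit & !snp_hit),
                    d = sum(!feat_hit & !snp_hit))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test with the condition-positive margin drawn from
#' the feature-positive/negative populations. The one-sided `"greater"`
#' alternative asks whether cell `a` is larger than expected at fixed
#' margins; the two-sided p-value is the sum of the probabilities of all
#' outcomes no more likely than the observed one (the convention of standard
#' statistical software). Probabilities are accumulated in log space, so
#' tables with counts in the hundreds of thousands are handled without
#' overflow. The odds ratio is the sample estimate `(a d)/(b c)`, with a 0.5
#' continuity correction applied to every cell when any cell is zero, and a
#' 95% Woolf (log-normal) confidence interval.
#'
#' @param t a [contingency_table()].
#' @param alternative `"greater"` (default, one-sided enrichment) or
#'   `"two_sided"`.
#' @return an `EnrichmentResult` with fields `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `neg_log10_p`, `method`, `alternative`.
#' @export
fisher_exact <- function(t, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  m <- a + c          # feature-positive population
  n_ <- b + d         # feature-negative population
  k <- a + b          # condition-positive draws
  lo <- max(0, k - n_); hi <- min(k, m)

  or_undefined <- FALSE
  if (m == 0 || n_ == 0 || k == 0 || (c + d) == 0) {
    # an all-zero margin: the observed outcome is the only possible one
    return(new_enrichment_result(NA_real_, NA_real_, NA_real_, 1, 0,
                                 "fisher", alternative, or_undefined = TRUE))
  }

  if (alternative == "greater") {
    log_p <- phyper(a - 1, m, n_, k, lower.tail = FALSE, log.p = TRUE)
  } else {
    supp <- lo:hi
    lp <- dhyper(supp, m, n_, k, log = TRUE)
    lp_obs <- dhyper(a, m, n_, k, log = TRUE)
    sel <- lp <= lp_obs + log1p(1e-7)   # relative-tolerance tie rule
    log_p <- logsumexp(lp[sel])
  }
  p <- min(1, exp(log_p))
  neg_log10_p <- max(0, -log_p / log(10))

  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log_or <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * 1.959963984540054 * se_log_or)
  new_enrichment_result(or, ci[1], ci[2], p, neg_log10_p,
                        "fisher", alternative, or_undefined = or_undefined)
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Cumulative-binomial open-chromatin enrichment
#'
#' Tests whether `x` of `n` SNPs in a phenotype fall into open chromatin more
#' often than expected given the fraction `p` of the uniquely mappable genome
#' that lies in open-chromatin regions containing assessed SNPs. The p-value
#' is the upper binomial tail `P(X >= x)` for `X ~ Binomial(n, p)`, evaluated
#' in log space; fold enrichment is `x / (n p)`.
#'
#' @param x overlap count (>= 0).
#' @param n total SNPs in the phenotype (> 0).
#' @param p success probability in (0, 1). Either give `p` directly or give
#'   `open_bp`, in which case `p = open_bp / mappable_genome_bp`.
#' @param open_bp open-chromatin base pairs containing assessed SNP regions.
#' @param mappable_genome_bp uniquely mappable genome size; the default is
#'   the uniquely mappable hg19 genome, 2,630,301,437 bp.
#' @return an `EnrichmentResult` with `method = "binomial"` and a
#'   `fold_enrichment` field.
#' @export
binomial_enrichment <- function(x, n, p = NULL, open_bp = NULL,
                                mappable_genome_bp = 2630301437) {
  if (is.null(p)) {
    if (is.null(open_bp)) stop("give either p or open_bp")
    p <- open_bp / mappable_genome_bp
  }
  if (!(p > 0 && p < 1)) stop("p must lie strictly in (0, 1)")
  if (!(n > 0)) stop("n must be > 0")
  if (x < 0 || x > n) stop("x must lie in [0, n]")
  log_p <- pbinom(x - 1, n, p, lower.tail = FALSE, log.p = TRUE)
  pv <- min(1, exp(log_p))
  new_enrichment_result(NA_real_, NA_real_, NA_real_, pv,
                        max(0, -log_p / log(10)),
                        "binomial", "greater",
                        fold_enrichment = x / (n * p))
}

#' Binned density profile of point features around centered regions
#'
#' Counts point features (SNP positions or motif-hit centers) in fixed-width
#' bins of signed offset relative to region centers, e.g. 100-bp bins across
#' a +/-1 kb window around centered open-chromatin regions. `centers` is
#' reduced to midpoints internally; each feature is assigned to its nearest
#' center on the same chromosome (ties to the leftmost center) and
#' contributes to the bin of its signed offset if |offset| < `window_bp`.
#' With the default global normalization, per-bin counts are divided by the
#' total number of reference centers so profiles are comparable across
#' datasets; `normalization = "per_bin"` instead divides by the total
#' in-window feature count.
#'
#' @param features a [peak_set()] of (ideally width-1) features; interval
#'   midpoints are used as the feature positions.
#' @param centers a [peak_set()] of reference regions.
#' @param window_bp half-window in bp (default 1000).
#' @param bin_bp bin width in bp (default 100); must divide `2 * window_bp`.
#' @param normalization `"global"` (default) or `"per_bin"`.
#' @return object of class `DensityProfile`: `bin_offsets` (bin centers,
#'   signed bp), `counts`, `normalized`, `window_bp`, `bin_bp`, `n_centers`,
#'   `n_features_in_window`.
#' @export
density_profile <- function(features, centers, window_bp = 1000, bin_bp = 100,
                            normalization = c("global", "per_bin")) {
  normalization <- match.arg(normalization)
  if ((2 * window_bp) %% bin_bp != 0) {
    stop("2 * window_bp must be divisible by bin_bp")
  }
  n_bins <- as.integer(2 * window_bp / bin_bp)
  counts <- integer(n_bins)
  cen <- ps_midpoints(centers)$intervals
  fea <- ps_midpoints(features)$intervals
  if (nrow(cen) > 0L && nrow(fea) > 0L) {
    for (chr in intersect(unique(cen$chrom), unique(fea$chrom))) {
      cp <- sort(cen$start[cen$chrom == chr])
      fp <- fea$start[fea$chrom == chr]
      # nearest center, ties to the leftmost (i.e. the earlier center wins)
      right <- findInterval(fp, cp) + 1L
      left <- pmax(right - 1L, 1L)
      right <- pmin(right, length(cp))
      d_left <- abs(fp - cp[left])
      d_right <- abs(fp - cp[right])
      nearest <- ifelse(d_left <= d_right, cp[left], cp[right])
      off <- fp - nearest
      inside <- off >= -window_bp & off < window_bp
      if (any(inside)) {
        bin <- floor((off[inside] + window_bp) / bin_bp) + 1L
        tab <- tabulate(bin, nbins = n_bins)
        counts <- counts + tab
      }
    }
  }
  total <- sum(counts)
  normalized <- if (normalization == "global") {
    if (nrow(cen) > 0L) counts / nrow(cen) else counts * NA_real_
  } else {
    if (total > 0) counts / total else counts * NA_real_
  }
  structure(list(
    bin_offsets = -window_bp + bin_bp / 2 + (seq_len(n_bins) - 1L) * bin_bp,
    counts = counts,
    normalized = normalized,
    window_bp = window_bp,
    bin_bp = bin_bp,
    normalization = normalization,
    n_centers = nrow(cen),
    n_features_in_window = total
  ), class = "DensityProfile")
}

#' @export
print.DensityProfile <- function(x, ...) {
  cat(sprintf("DensityProfile: %d bins of %d bp over +/-%d bp, %d features in window (%d centers)\n",
              length(x$counts), x$bin_bp, x$window_bp,
              x$n_features_in_window, x$n_centers))
  invisible(x)
}
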