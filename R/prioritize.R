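# The candidate-variant funnel: peak-set overlap combination and
# annotation-based functional filtering.

#' Flag variants by overlap with epigenomic peak sets
#'
#' Each variant is tested for 1-bp containment (half-open intervals: a SNP at
#' `pos == end` is outside) in open chromatin, active-enhancer and
#' TF-binding peaks. TF binding is the union of the supplied TF peak sets
#' (per-factor flags are retained for auditing). The `combined` flag is the
#' AND of the three overlap flags.
#'
#' @param variants a [variant_table()].
#' @param atac a [peak_set()] of open-chromatin regions.
#' @param h3k27ac a [peak_set()] of active-enhancer regions.
#' @param tf a [peak_set()] or a list of them (one per factor).
#' @return data.frame: `rsid`, `chrom`, `pos`, `in_open_chromatin`,
#'   `in_h3k27ac`, `in_tf_binding`, `combined`, plus one `in_tf_<label>`
#'   column per TF set when a list is given.
#' @export
overlap_combination <- function(variants, atac, h3k27ac, tf) {
  tf_list <- if (inherits(tf, "PeakSet")) list(tf) else tf
  stopifnot(length(tf_list) >= 1L)
  lev <- unique(c(normalize_chrom(variants$chrom),
                  atac$intervals$chrom, h3k27ac$intervals$chrom,
                  unlist(lapply(tf_list, function(p) p$intervals$chrom)),
                  "chr1"))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = factor(normalize_chrom(variants$chrom), levels = lev),
    ranges = IRanges::IRanges(start = variants$pos + 1, width = 1)
  )
  contains <- function(ps) {
    if (nrow(ps$intervals) == 0L) return(rep(FALSE, length(snp_gr)))
    GenomicRanges::countOverlaps(snp_gr, ps_granges(ps, lev)) > 0
  }
  out <- data.frame(rsid = variants$rsid,
                    chrom = normalize_chrom(variants$chrom),
                    pos = variants$pos,
                    in_open_chromatin = contains(atac),
                    in_h3k27ac = contains(h3k27ac),
                    stringsAsFactors = FALSE)
  per_tf <- vapply(tf_list, contains, logical(nrow(out)))
  per_tf <- matrix(per_tf, nrow = nrow(out))
  out$in_tf_binding <- rowSums(per_tf) > 0
  if (length(tf_list) > 1L) {
    labels <- vapply(tf_list, function(p) p$label, character(1))
    colnames(per_tf) <- paste0("in_tf_", labels)
    out <- cbind(out, per_tf)
  }
  out$combined <- out$in_open_chromatin & out$in_h3k27ac & out$in_tf_binding
  out
}

#' Filter candidates on functional-annotation evidence
#'
#' Retains candidates whose regulatory functional-score category (1-6, lower
#' = stronger evidence, RegulomeDB-style, consumed as an input table) is at
#' most `max_score` and which show in-vivo protein binding by at least
#' `min_factors` trans-acting factors. Candidates without a score are
#' dropped and counted (attribute `"n_unscored"`).
#'
#' @param candidates data.frame with an `rsid` column (e.g. from
#'   [overlap_combination()]).
#' @param annotations data.frame `rsid`, `functional_score`,
#'   `n_bound_factors`.
#' @param max_score maximum functional-score category kept (default 4).
#' @param min_factors minimum bound-factor count kept (default 1).
#' @return the retained rows of `candidates` with `functional_score` and
#'   `n_bound_factors` merged in.
#' @export
functional_filter <- function(candidates, annotations, max_score = 4L,
                              min_factors = 1L) {
  stopifnot(all(c("rsid", "functional_score", "n_bound_factors")
                %in% names(annotations)))
  out <- merge(candidates, annotations, by = "rsid", all.x = TRUE,
               sort = FALSE)
  n_unscored <- sum(is.na(out$functional_score))
  if (n_unscored) {
    message(n_unscored, " candidate(s) lack a functional score and were dropped")
  }
  keep <- !is.na(out$functional_score) &
    out$functional_score <= max_score &
    !is.na(out$n_bound_factors) &
    out$n_bound_factors >= min_factors
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unscored") <- n_unscored
  out
}

#' Run the full prioritization funnel
#'
#' Convenience wrapper chaining LD expansion, epigenomic overlap combination
#' and functional filtering, returning each stage and its count (the shape of
#' the candidate funnel).
#'
#' @param leads,ld,panel passed to [expand_ld()].
#' @param atac,h3k27ac,tf passed to [overlap_combination()].
#' @param annotations passed to [functional_filter()].
#' @param r2_min,max_score,min_factors stage cutoffs.
#' @return list with `expanded` (variant table), `flags` (full flag matrix),
#'   `combined` (all-three-overlap candidates), `filtered` (post-annotation
#'   candidates) and `counts` (named vector of funnel sizes).
#' @export
prioritization_funnel <- function(leads, ld, panel, atac, h3k27ac, tf,
                                  annotations, r2_min = 0.8,
                                  max_score = 4L, min_factors = 1L) {
  expanded <- expand_ld(leads, ld, panel, r2_min = r2_min)
  flags <- overlap_combination(expanded, atac, h3k27ac, tf)
  combined <- flags[flags$combined, , drop = FALSE]
  filtered <- functional_filter(combined, annotations,
                                max_score = max_score,
                                min_factors = min_factors)
  list(expanded = expanded, flags = flags, combined = combined,
       filtered = filtered,
       counts = c(candidates = nrow(expanded),
                  open_chromatin = sum(flags$in_open_chromatin),
                  h3k27ac = sum(flags$in_h3k27ac),
                  tf_binding = sum(flags$in_tf_binding),
                  combined = nrow(combined),
                  filtered = nrow(filtered)))
}
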