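# LD expansion of lead GWAS SNPs and transcribed-proxy selection.
#
# LD is consumed as an input table (pairwise r2 and |D'| between a lead and a
# proxy, tagged by reference population), as obtained from 1000 Genomes-style
# browsers; it is never computed from genotypes here.

#' Construct a variant table
#'
#' Validates and normalizes a table of variants (one row per SNP). Positions
#' are 0-based, consistent with the interval conventions of [peak_set()].
#'
#' @param df data.frame with columns `rsid`, `chrom`, `pos` and optionally
#'   `ref_allele`, `alt_allele`, `risk_allele`, `maf`.
#' @return a validated data.frame of class `c("variant_table", "data.frame")`.
#' @export
variant_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("rsid", "chrom", "pos")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- df
  out$rsid <- as.character(out$rsid)
  out$chrom <- normalize_chrom(as.character(out$chrom))
  out$pos <- as.numeric(out$pos)
  if (any(out$pos < 0 | is.na(out$pos))) stop("variant positions must be >= 0")
  if (all(c("ref_allele", "alt_allele") %in% names(out))) {
    same <- !is.na(out$ref_allele) & !is.na(out$alt_allele) &
      out$ref_allele == out$alt_allele
    if (any(same)) {
      stop("ref_allele equals alt_allele for: ",
           paste(head(out$rsid[same], 5L), collapse = ", "))
    }
  }
  if ("maf" %in% names(out)) {
    bad <- !is.na(out$maf) & (out$maf < 0 | out$maf > 0.5)
    if (any(bad)) stop("maf must lie in [0, 0.5]")
  }
  if (anyDuplicated(out$rsid)) {
    stop("duplicated rsid(s) in variant table")
  }
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Validate an LD table
#'
#' Pairwise linkage records `(lead_rsid, proxy_rsid, r2, dprime, population)`.
#' Both `r2` and `dprime` must lie in `[0, 1]`. The theoretical relation
#' `r2 <= dprime^2` is *not* enforced, since browser-derived tables can be
#' internally inconsistent; violations are counted and reported as a message.
#'
#' @param df data.frame with columns `lead_rsid`, `proxy_rsid`, `r2`,
#'   `dprime` and optionally `population`.
#' @return the validated data.frame.
#' @export
ld_table <- function(df) {
  stopifnot(is.data.frame(df))
  req <- c("lead_rsid", "proxy_rsid", "r2", "dprime")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("LD table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE)) stop("r2 must lie in [0, 1]")
  if (any(df$dprime < 0 | df$dprime > 1, na.rm = TRUE)) {
    stop("dprime must lie in [0, 1]")
  }
  n_bad <- sum(df$r2 > df$dprime^2 + 1e-9, na.rm = TRUE)
  if (n_bad > 0) {
    message(n_bad, " LD record(s) violate r2 <= dprime^2 (kept; input data ",
            "may be inconsistent)")
  }
  if (!"population" %in% names(df)) {
    df$population <- rep(NA_character_, nrow(df))
  }
  df
}

#' Expand lead SNPs to their high-LD candidate set
#'
#' Returns the union of the lead variants and every proxy linked to any lead
#' at `r2 >= r2_min` (inclusive threshold), deduplicated by rsid. Leads are
#' always retained, whether or not they appear in the LD table. Proxies whose
#' rsid cannot be resolved in `panel` are skipped with a warning reporting the
#' count.
#'
#' @param leads [variant_table()] of lead GWAS SNPs.
#' @param ld [ld_table()] of pairwise linkage records.
#' @param panel [variant_table()] resolving proxy rsids to coordinates.
#' @param r2_min squared-correlation cutoff (default 0.8).
#' @return a [variant_table()] with a logical column `is_lead`.
#' @export
expand_ld <- function(leads, ld, panel, r2_min = 0.8) {
  stopifnot(r2_min >= 0, r2_min <= 1)
  ld <- ld_table(ld)
  hits <- ld[ld$lead_rsid %in% leads$rsid & ld$r2 >= r2_min, , drop = FALSE]
  proxy_ids <- setdiff(unique(hits$proxy_rsid), leads$rsid)
  unresolved <- setdiff(proxy_ids, panel$rsid)
  if (length(unresolved)) {
    warning(length(unresolved),
            " proxy rsid(s) have no coordinate record and were skipped")
  }
  proxies <- panel[panel$rsid %in% proxy_ids, , drop = FALSE]
  cols <- intersect(names(leads), names(proxies))
  out <- rbind(as.data.frame(leads)[, cols, drop = FALSE],
               as.data.frame(proxies)[, cols, drop = FALSE])
  out$is_lead <- out$rsid %in% leads$rsid
  out <- out[!duplicated(out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  variant_table(out)
}

#' Select a transcribed proxy marker for an allelic-expression assay
#'
#' Allelic expression imbalance is measured at a transcribed marker SNP
#' co-inherited with the candidate regulatory SNP. Linked markers are
#' accepted at `|D'| > dprime_strict` (default 0.90); moderately linked
#' markers with `|D'| > dprime_relaxed` (default 0.75) are used as a
#' fallback. Markers must have minor allele frequency above `maf_min`
#' (default 0.15) so enough heterozygotes can be found. Among eligible
#' markers the one with maximal `|D'|` is chosen; ties break by higher MAF,
#' then lexicographic rsid. If no marker qualifies, `NULL` is returned — the
#' caller may then measure the candidate SNP itself in pre-mRNA (intronic
#' transcript) as a transcription surrogate.
#'
#' @param candidate_rsid rsid of the candidate regulatory SNP.
#' @param transcribed [variant_table()] of transcribed SNPs carrying `maf`.
#' @param ld [ld_table()] linking the candidate (as `lead_rsid`) to markers.
#' @param dprime_strict,dprime_relaxed,maf_min selection cutoffs.
#' @return a single-row [variant_table()] with a `dprime` column, or `NULL`.
#' @export
select_transcribed_proxy <- function(candidate_rsid, transcribed, ld,
                                     dprime_strict = 0.90,
                                     dprime_relaxed = 0.75,
                                     maf_min = 0.15) {
  if (!"maf" %in% names(transcribed) || anyNA(transcribed$maf)) {
    stop("transcribed SNPs must carry maf")
  }
  ld <- ld_table(ld)
  links <- ld[ld$lead_rsid == candidate_rsid &
                ld$proxy_rsid %in% transcribed$rsid, , drop = FALSE]
  if (nrow(links) == 0L) return(NULL)
  cand <- merge(links, as.data.frame(transcribed),
                by.x = "proxy_rsid", by.y = "rsid")
  cand <- cand[cand$maf > maf_min, , drop = FALSE]
  pick <- function(cut) {
    ok <- cand[cand$dprime > cut, , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
    ok <- ok[order(-ok$dprime, -ok$maf, ok$proxy_rsid), , drop = FALSE]
    ok[1L, , drop = FALSE]
  }
  best <- pick(dprime_strict)
  if (is.null(best)) best <- pick(dprime_relaxed)
  if (is.null(best)) return(NULL)
  out <- best[, c("proxy_rsid", "chrom", "pos",
                  intersect(c("maf"), names(best)), "dprime"), drop = FALSE]
  names(out)[1] <- "rsid"
  rownames(out) <- NULL
  variant_table(out)
}
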