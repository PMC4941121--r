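# Genomic-interval data model and overlap arithmetic.
#
# All coordinates are 0-based half-open (the BED convention), including SNP
# positions, which are stored as width-1 intervals. Chromosome names are
# normalized to the "chr"-prefixed dialect on construction. Strand is ignored
# for interval arithmetic; it only matters inside motif scanning.

#' Construct a PeakSet
#'
#' A `PeakSet` is the universal unit of interval arithmetic in the pipeline: a
#' labelled, assembly-tagged collection of half-open genomic intervals with an
#' optional signal score (e.g. peak intensity) and an optional name.
#' Intervals are validated (`0 <= start < end`) and sorted by
#' `(chrom, start, end)` at construction.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` and `score`. Chromosome names lacking a `"chr"` prefix
#'   are normalized to the prefixed form.
#' @param label dataset name.
#' @param genome_id assembly tag; interval operations refuse to mix peak sets
#'   from different assemblies.
#' @return An object of class `PeakSet`.
#' @examples
#' ps <- peak_set(data.frame(chrom = "chr1", start = 0, end = 100))
#' @export
peak_set <- function(intervals, label = "peaks", genome_id = "synthetic") {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) == 0L) {
    intervals <- data.frame(chrom = character(), start = integer(),
                            end = integer(), name = character(),
                            score = numeric(), stringsAsFactors = FALSE)
  }
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(intervals))
  if (length(missing_cols)) {
    stop("intervals lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- data.frame(
    chrom = normalize_chrom(as.character(intervals$chrom)),
    start = as.numeric(intervals$start),
    end   = as.numeric(intervals$end),
    name  = if ("name" %in% names(intervals))
      as.character(intervals$name) else NA_character_,
    score = if ("score" %in% names(intervals))
      as.numeric(intervals$score) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- which(!(df$start < df$end) | df$start < 0 |
                 is.na(df$start) | is.na(df$end))
  if (length(bad)) {
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5L), collapse = ", "),
         ": need 0 <= start < end")
  }
  if (any(!is.na(df$score) & df$score < 0)) {
    stop("interval scores must be non-negative")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(label = label, genome_id = genome_id, intervals = df),
            class = "PeakSet")
}

normalize_chrom <- function(x) {
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s' (%s): %d intervals, %s bp covered\n",
              x$label, x$genome_id, nrow(x$intervals),
              format(ps_covered_bp(x), big.mark = ",")))
  if (nrow(x$intervals)) print(head(x$intervals, 6L))
  invisible(x)
}

#' @export
length.PeakSet <- function(x) nrow(x$intervals)

#' @export
as.data.frame.PeakSet <- function(x, ...) x$intervals

## GRanges view of a PeakSet (1-based closed, as IRanges expects).
ps_granges <- function(ps, seqlevels = NULL) {
  df <- ps$intervals
  if (is.null(seqlevels)) seqlevels <- unique(df$chrom)
  if (length(seqlevels) == 0L) seqlevels <- "chr1"
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

common_levels <- function(a, b) {
  unique(c(a$intervals$chrom, b$intervals$chrom, "chr1"))
}

check_same_genome <- function(a, b) {
  if (!identical(a$genome_id, b$genome_id)) {
    stop("peak sets are on different assemblies: '", a$genome_id,
         "' vs '", b$genome_id, "'")
  }
}

#' Total covered bases of a PeakSet
#'
#' Length of the union of all intervals (overlaps counted once), in bp.
#'
#' @param ps a [peak_set()].
#' @return non-negative integer number of covered base pairs.
#' @export
ps_covered_bp <- function(ps) {
  if (nrow(ps$intervals) == 0L) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(ps_granges(ps))))
}

#' Read a BED file into a PeakSet
#'
#' Accepts the 3-6 column BED dialect (chrom, start, end, name, score,
#' strand); coordinates are 0-based half-open. `track`/`browser`/comment lines
#' are skipped. Strand, if present, is ignored (peaks are unstranded here).
#' Malformed records are reported with their line numbers.
#'
#' @param path file to read.
#' @inheritParams peak_set
#' @return a [peak_set()].
#' @export
read_bed <- function(path, label = basename(path), genome_id = "synthetic") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  errors <- character()
  rows <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    ln <- idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || length(f) > 6L) {
      errors <- c(errors, sprintf("line %d: expected 3-6 tab-separated fields, got %d",
                                  ln, length(f)))
      next
    }
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end)) {
      errors <- c(errors, sprintf("line %d: non-numeric coordinates", ln))
      next
    }
    if (!(start < end) || start < 0) {
      errors <- c(errors, sprintf("line %d: malformed coordinates (end <= start or start < 0)", ln))
      next
    }
    name <- if (length(f) >= 4L && f[4] != ".") f[4] else NA_character_
    score <- if (length(f) >= 5L && f[5] != ".")
      suppressWarnings(as.numeric(f[5])) else NA_real_
    rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                            name = name, score = score,
                            stringsAsFactors = FALSE)
  }
  if (length(errors)) {
    stop("BED parse error(s) in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(chrom = character(), start = numeric(),
                                    end = numeric())
  peak_set(df, label = label, genome_id = genome_id)
}

#' Write a PeakSet to a BED file
#'
#' Writes BED3 when neither names nor scores are present, BED4 with names
#' only, and BED5 when any score is present (missing names become `"."`,
#' missing scores `0`). `read_bed(write_bed(x))` round-trips the retained
#' columns.
#'
#' @param ps a [peak_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  df <- ps$intervals
  has_name <- any(!is.na(df$name))
  has_score <- any(!is.na(df$score))
  cols <- list(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  if (has_name || has_score) {
    cols <- c(cols, list(ifelse(is.na(df$name), ".", df$name)))
  }
  if (has_score) {
    cols <- c(cols, list(ifelse(is.na(df$score), 0, df$score)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Intervals of one set overlapping another
#'
#' Returns the intervals of `a` that have at least `min_overlap_bp` base pairs
#' of overlap with any interval of `b`; each interval of `a` is reported at
#' most once. Adjacency under the half-open convention (an interval ending
#' where another starts) is not overlap.
#'
#' @param a,b [peak_set()] objects on the same assembly.
#' @param min_overlap_bp minimum required overlap in bp (default 1).
#' @return a [peak_set()], a subset of `a`.
#' @export
ps_intersect <- function(a, b, min_overlap_bp = 1L) {
  check_same_genome(a, b)
  stopifnot(min_overlap_bp >= 1)
  if (nrow(a$intervals) == 0L || nrow(b$intervals) == 0L) {
    return(peak_set(a$intervals[0, ], label = a$label, genome_id = a$genome_id))
  }
  lev <- common_levels(a, b)
  ov <- GenomicRanges::findOverlaps(ps_granges(a, lev), ps_granges(b, lev),
                                    minoverlap = min_overlap_bp)
  keep <- sort(unique(S4Vectors::queryHits(ov)))
  peak_set(a$intervals[keep, , drop = FALSE], label = a$label,
           genome_id = a$genome_id)
}

#' Merge overlapping or nearby intervals
#'
#' Produces unique, non-overlapping intervals: members separated by a gap of
#' at most `gap_bp` on the same chromosome are collapsed into their spanning
#' interval, whose score is the mean of the member scores. With the default
#' `gap_bp = 0`, overlapping and book-ended intervals merge and the union of
#' covered bases is preserved. The operation is idempotent.
#'
#' @param a a [peak_set()].
#' @param gap_bp maximum gap (bp) across which intervals are still merged.
#' @return a [peak_set()] whose intervals are pairwise separated by more than
#'   `gap_bp`.
#' @export
ps_merge <- function(a, gap_bp = 0L) {
  stopifnot(gap_bp >= 0)
  if (nrow(a$intervals) == 0L) return(a)
  gr <- ps_granges(a)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap_bp + 1)
  ov <- GenomicRanges::findOverlaps(gr, red, maxgap = gap_bp)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  # each original interval belongs to exactly one merged region
  score <- tapply(a$intervals$score, grp, function(s) {
    s <- s[!is.na(s)]
    if (length(s)) mean(s) else NA_real_
  })
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1,
    end = GenomicRanges::end(red),
    score = as.numeric(score[as.character(seq_along(red))]),
    stringsAsFactors = FALSE
  )
  peak_set(df, label = a$label, genome_id = a$genome_id)
}

#' Replace intervals by their 1-bp centers
#'
#' Each interval becomes the single base `floor((start + end) / 2)`; for
#' even-length intervals this is the lower-middle base, matching common
#' peak-summit tooling. Interval count, names and scores are preserved.
#'
#' @param a a [peak_set()].
#' @return a [peak_set()] of width-1 intervals.
#' @export
ps_midpoints <- function(a) {
  df <- a$intervals
  mid <- floor((df$start + df$end) / 2)
  df$start <- mid
  df$end <- mid + 1
  peak_set(df, label = a$label, genome_id = a$genome_id)
}

#' Filter intervals by minimum length
#'
#' Keeps exactly the intervals with `end - start >= min_bp`. Used to drop
#' sub-threshold slivers (e.g. interval edges not identically called across
#' datasets) before variance-sensitive downstream analyses.
#'
#' @param a a [peak_set()].
#' @param min_bp minimum interval width in bp (inclusive).
#' @return a [peak_set()].
#' @export
ps_filter_by_length <- function(a, min_bp) {
  stopifnot(min_bp >= 1)
  df <- a$intervals
  keep <- (df$end - df$start) >= min_bp
  peak_set(df[keep, , drop = FALSE], label = a$label, genome_id = a$genome_id)
}
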