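# Null-structured feature construction for enrichment calibration.

#' Draw a feature peak set as a random subset of a background universe
#'
#' Emulates the no-enrichment null for the DHS-background contingency test:
#' a cell type's feature peaks (e.g. open chromatin) are a random subset of
#' the pan-cell-type DHS universe, chosen independently of interval length
#' and of SNP positions. Under this construction the feature/SNP
#' classification of [build_dhs_contingency()] is exactly independent, so
#' the one-sided Fisher test should reject at close to its nominal level.
#'
#' @param universe a [peak_set()] (the DHS background).
#' @param fraction inclusion probability per interval (default 0.4).
#' @param seed integer seed.
#' @param label label of the returned set.
#' @return a [peak_set()] that is a subset of `universe`.
#' @export
sample_feature_subset <- function(universe, fraction = 0.4, seed = 1L,
                                  label = "feature") {
  stopifnot(fraction > 0, fraction <= 1)
  keep <- withr::with_seed(as.integer(seed), {
    runif(nrow(universe$intervals)) < fraction
  })
  peak_set(universe$intervals[keep, , drop = FALSE], label = label,
           genome_id = universe$genome_id)
}
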