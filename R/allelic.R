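# Allele-specific quantification: mixing-series calibration of two-allele
# fluorescence ratios, allelic-ratio estimation with genomic-DNA
# normalization, and imbalance testing (allelic expression imbalance and
# allele-specific ChIP).
#
# The forward model: a genotyping assay on a known allele1:allele2 mix ratio
# m reads out log2(channel1/channel2) ~= slope * log2(m) + intercept. cDNA
# and gDNA measurements from a heterozygote are inverted through that curve,
# and the gDNA ratio (truth: 1 for a heterozygote) normalizes away
# probe/assay bias. All logs are base 2.

#' Fit a mixing-series calibration curve
#'
#' Ordinary least-squares fit of the measured log2 intensity ratio against
#' `log2(mix_ratio)` over a standard mixing series (canonically 8:1, 4:1,
#' 2:1, 1:1, 1:2, 1:4, 1:8 — log2 design points 3..-3).
#'
#' @param points data.frame with columns `mix_ratio` (known allele1:allele2
#'   ratio, > 0) and `log2_intensity_ratio` (measured, e.g. VIC/FAM at the
#'   final cycle). At least 3 points with non-constant `mix_ratio`.
#' @return object of class `CalibrationCurve`: `slope`, `intercept`,
#'   `r_squared`, `n_points`.
#' @export
fit_calibration <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("mix_ratio", "log2_intensity_ratio") %in% names(points)))
  if (nrow(points) < 3L) stop("calibration needs at least 3 points")
  if (any(points$mix_ratio <= 0)) stop("mix_ratio must be > 0")
  x <- log2(points$mix_ratio)
  if (var(x) == 0) stop("mix_ratio has zero variance; cannot fit a curve")
  fit <- lm(points$log2_intensity_ratio ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(points)),
            class = "CalibrationCurve")
}

#' @export
print.CalibrationCurve <- function(x, ...) {
  cat(sprintf("CalibrationCurve: slope %.4f, intercept %.4f, r^2 %.4f (%d points)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Normalized allelic ratio from paired cDNA/gDNA measurements
#'
#' Inverts the calibration curve for the cDNA and gDNA log2 intensity ratios
#' of a heterozygous sample and returns the cDNA allelic ratio normalized by
#' the gDNA allelic ratio (equivalently, the log2 ratios are subtracted
#' before back-transforming). A value of 1.0 means no imbalance; swapping the
#' allele labels inverts the value exactly. Vectorized over measurements.
#'
#' @param cdna_log2_ratio,gdna_log2_ratio measured log2 intensity ratios
#'   (replicates should be averaged on the log2 scale beforehand; see
#'   [average_replicates_log2()]).
#' @param curve a [fit_calibration()] result with non-zero slope.
#' @return numeric vector of normalized allelic ratios.
#' @export
quantify_allelic_ratio <- function(cdna_log2_ratio, gdna_log2_ratio, curve) {
  if (abs(curve$slope) < 1e-8) {
    stop("calibration curve slope is ~0; curve is not invertible")
  }
  log2_cdna <- (cdna_log2_ratio - curve$intercept) / curve$slope
  log2_gdna <- (gdna_log2_ratio - curve$intercept) / curve$slope
  2^(log2_cdna - log2_gdna)
}

#' Average replicate measurements on the log2 scale
#'
#' @param x numeric vector of log2 ratios (e.g. a triplicate).
#' @return their mean, NA values dropped.
#' @export
average_replicates_log2 <- function(x) mean(x, na.rm = TRUE)

#' Test allelic ratios against the balanced expectation
#'
#' One-sample Student's t-test of the observed normalized allelic ratios
#' against the expected ratio under no imbalance (1.0), two-tailed. Constant
#' input equal to the expectation returns `t = 0, p = 1` by contract.
#'
#' @param ratios numeric vector of normalized allelic ratios (n >= 2).
#' @param expected null ratio (default 1.0).
#' @return list with `t`, `df`, `p_value`, `mean_ratio`, `n`.
#' @export
aei_test <- function(ratios, expected = 1.0) {
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < 2L) stop("aei_test needs at least 2 ratios")
  if (sd(ratios) == 0) {
    if (all(ratios == expected)) {
      return(list(t = 0, df = n - 1, p_value = 1,
                  mean_ratio = expected, n = n))
    }
    stop("ratios have zero variance and differ from the expected value")
  }
  ht <- t.test(ratios, mu = expected)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_ratio = mean(ratios), n = n)
}

#' Per-antibody allelic enrichment from allele-specific ChIP
#'
#' For each antibody group, replicate log2 ratios are averaged per sample on
#' the log2 scale, converted to normalized allelic ratios through the
#' calibration curve ([quantify_allelic_ratio()]), and compared with the
#' control group (chromatin input) by an unpaired two-tailed Welch t-test.
#' Groups whose mean assay signal falls below `min_signal` (e.g. an IgG
#' pulldown that captured essentially nothing) are flagged and excluded from
#' ratio estimation.
#'
#' @param measurements data.frame with columns `antibody`, `sample_id`,
#'   `cdna_log2_ratio` (the immunoprecipitate ratio), `gdna_log2_ratio`, and
#'   optionally `replicate` and `signal` (a per-measurement assay intensity
#'   used only for the low-signal flag).
#' @param curve a [fit_calibration()] result.
#' @param control name of the control group (default `"input"`); must be
#'   present and not low-signal.
#' @param min_signal absolute signal threshold below which a group is
#'   flagged (default 0.05); only applied when a `signal` column exists.
#' @return data.frame with one row per non-control antibody: `antibody`,
#'   `mean_ratio`, `n_samples`, `t`, `df`, `p_value`. Flagged groups are
#'   listed in attribute `"low_signal"`.
#' @export
haplochip_allele_enrichment <- function(measurements, curve,
                                        control = "input",
                                        min_signal = 0.05) {
  req <- c("antibody", "sample_id", "cdna_log2_ratio", "gdna_log2_ratio")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols)) {
    stop("measurements lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  low <- character()
  if ("signal" %in% names(measurements)) {
    gmean <- tapply(measurements$signal, measurements$antibody,
                    mean, na.rm = TRUE)
    low <- names(gmean)[gmean < min_signal]
    if (length(low)) {
      measurements <- measurements[!measurements$antibody %in% low, ,
                                   drop = FALSE]
    }
  }
  if (!control %in% measurements$antibody) {
    stop("control group '", control, "' is missing",
         if (control %in% low) " (flagged as low-signal)" else "")
  }
  per_sample <- function(group) {
    sub <- measurements[measurements$antibody == group, , drop = FALSE]
    cd <- tapply(sub$cdna_log2_ratio, sub$sample_id, average_replicates_log2)
    gd <- tapply(sub$gdna_log2_ratio, sub$sample_id, average_replicates_log2)
    quantify_allelic_ratio(as.numeric(cd), as.numeric(gd), curve)
  }
  ctrl_ratios <- per_sample(control)
  groups <- setdiff(unique(measurements$antibody), control)
  rows <- lapply(groups, function(g) {
    r <- per_sample(g)
    ht <- t.test(r, ctrl_ratios)   # Welch by default
    data.frame(antibody = g, mean_ratio = mean(r), n_samples = length(r),
               t = unname(ht$statistic), df = unname(ht$parameter),
               p_value = ht$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "low_signal") <- low
  attr(out, "control_mean_ratio") <- mean(ctrl_ratios)
  out
}
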