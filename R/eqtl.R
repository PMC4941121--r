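# Linear-model cis-eQTL association and conditional residual-regression
# analysis.
#
# Expression is modelled as a linear function of allele dosage (0/1/2). The
# conditional analysis P(SNP1 | SNP2) residualizes expression on SNP2 by
# ordinary least squares and then tests SNP1 against the residuals; for a
# single conditioning SNP the t-test p-value is identical whichever side of
# the regression is residualized, so the directional ambiguity is moot.

check_dosage <- function(g, arg = "genotype") {
  if (anyNA(g)) stop(arg, " contains NA")
  if (!all(g %in% c(0, 1, 2))) stop(arg, " dosages must be 0, 1 or 2")
  invisible(g)
}

#' Single-SNP linear eQTL association
#'
#' Ordinary least-squares regression of (normalized, log2-scale) expression
#' on allele dosage, with the usual t-test on the slope.
#'
#' @param genotype dosage vector in {0, 1, 2}; must be polymorphic.
#' @param expression numeric vector, same length (n >= 3).
#' @param covariates optional numeric matrix of adjustment covariates
#'   (default none).
#' @return list with `beta`, `se`, `t`, `p_value`, `df`, `n`.
#' @export
eqtl_linear <- function(genotype, expression, covariates = NULL) {
  check_dosage(genotype)
  n <- length(genotype)
  if (length(expression) != n) stop("genotype/expression length mismatch")
  if (n < 3L) stop("need at least 3 samples")
  if (var(genotype) == 0) stop("monomorphic genotype: no association testable")
  if (is.null(covariates)) {
    fit <- lm(expression ~ genotype)
  } else {
    covariates <- as.matrix(covariates)
    fit <- lm(expression ~ genotype + covariates)
  }
  sm <- summary(fit)$coefficients
  list(beta = sm["genotype", 1], se = sm["genotype", 2],
       t = sm["genotype", 3], p_value = sm["genotype", 4],
       df = fit$df.residual, n = n)
}

#' Conditional eQTL association P(SNP1 | SNP2)
#'
#' Tests whether SNP1 carries association signal beyond SNP2: expression is
#' residualized on SNP2 (ordinary least squares), and SNP1 is tested against
#' the residuals. A proxy SNP whose marginal signal is purely due to LD with
#' the causal SNP is nullified by conditioning on it. Perfect collinearity
#' (r^2 = 1 between the two genotypes) leaves no testable signal; the result
#' is flagged `collinear` and the conditional p-value is ~1 by construction.
#'
#' @param snp1 dosage vector being tested.
#' @param snp2 dosage vector being conditioned on.
#' @param expression numeric vector, same length.
#' @return list with `beta`, `se`, `p_value`, `r2_snps` (squared dosage
#'   correlation of the two SNPs) and logical `collinear`.
#' @export
conditional_eqtl <- function(snp1, snp2, expression) {
  check_dosage(snp1, "snp1")
  check_dosage(snp2, "snp2")
  n <- length(expression)
  stopifnot(length(snp1) == n, length(snp2) == n)
  if (var(snp1) == 0 || var(snp2) == 0) {
    stop("both genotypes must be polymorphic")
  }
  r <- cor(snp1, snp2)
  collinear <- abs(r) > 1 - 1e-12
  res <- residuals(lm(expression ~ snp2))
  fit <- lm(res ~ snp1)
  sm <- summary(fit)$coefficients
  list(beta = sm["snp1", 1], se = sm["snp1", 2], p_value = sm["snp1", 4],
       r2_snps = r^2, collinear = collinear)
}

#' Scan genes in a cis window around a candidate SNP
#'
#' Tests the candidate SNP against every gene whose position lies within
#' `cis_window` bp centered on the SNP, returning associations up to the
#' reporting p-value ceiling.
#'
#' @param cohort a cohort as produced by [generate_eqtl_cohort()]: a list
#'   with `genotypes` (n x SNPs dosage matrix), `expression` (n x genes
#'   matrix), `snp_pos` (data.frame `rsid`, `chrom`, `pos`) and `gene_pos`
#'   (data.frame `gene`, `chrom`, `pos`).
#' @param rsid candidate SNP identifier (a column of `genotypes`).
#' @param cis_window full window width in bp centered on the SNP
#'   (default 2,000,000).
#' @param max_p reporting ceiling on the association p-value (default 0.05).
#' @return data.frame `gene`, `beta`, `se`, `p_value`, ordered by p-value.
#' @export
eqtl_scan <- function(cohort, rsid, cis_window = 2e6, max_p = 0.05) {
  if (!rsid %in% colnames(cohort$genotypes)) stop("unknown SNP: ", rsid)
  g <- cohort$genotypes[, rsid]
  sp <- cohort$snp_pos[cohort$snp_pos$rsid == rsid, , drop = FALSE]
  gp <- cohort$gene_pos
  in_cis <- gp$chrom == sp$chrom & abs(gp$pos - sp$pos) <= cis_window / 2
  genes <- gp$gene[in_cis]
  rows <- lapply(genes, function(gene) {
    fit <- eqtl_linear(g, cohort$expression[, gene])
    data.frame(gene = gene, beta = fit$beta, se = fit$se,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene = character(), beta = numeric(), se = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[out$p_value <= max_p, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
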