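# Synthetic-data generators with known ground truth.
#
# Every generator is a pure function of (config, arguments): the RNG state is
# locally seeded from config$seed (plus a fixed per-generator offset so the
# stages draw independent streams) and restored afterwards, so identical
# configs give byte-identical data. Truth (planted motif positions, SNP
# labels, LD structure, allelic ratios, effect sizes) is always returned
# alongside the data so downstream recovery is assertable mechanically.

GENOME_SEED_OFFSET  <- 101L
SNP_SEED_OFFSET    <- 202L
PEAK_SEED_OFFSET   <- 303L
ALLELIC_SEED_OFFSET <- 404L
EQTL_SEED_OFFSET   <- 505L

#' Simulation configuration
#'
#' Desk-scale defaults: a 1-Mb genome with 200 planted motifs, 100 case and
#' 100 control SNPs, a 23-heterozygote allelic series and an n = 500 eQTL
#' cohort — every stage completes in seconds to minutes. GC content defaults
#' to 0.41 (human-like); the allelic defaults (true ratio 1.3, log2 noise sd
#' 0.1, n = 23) mirror a realistic single-locus allelic-imbalance design,
#' and the eQTL defaults (beta = 0.4 on log2 expression, unit residual sd,
#' MAF 0.3) a well-powered single-tissue association.
#'
#' @param seed integer master seed.
#' @param genome_length_bp,gc_fraction genome simulation parameters.
#' @param n_planted_motifs number of motif instances planted.
#' @param n_case_snps,n_control_snps SNP panel sizes.
#' @param fraction_snps_near_motif fraction of case SNPs placed within
#'   `near_distance_bp` of a planted motif center.
#' @param near_distance_bp proximity radius for "near-motif" placement (bp).
#' @param peak_width_mean_bp mean synthetic peak width (bp).
#' @param n_random_peaks background (non-motif) peaks per peak set.
#' @param ld_block_size case SNPs per LD block (>= 2 gives each lead at
#'   least one perfect proxy).
#' @param proxy_r2_range range from which additional proxy r2 values are
#'   drawn (the first proxy of each block is always r2 = 1).
#' @param true_allelic_ratio,allelic_noise_sd,n_heterozygotes allelic assay
#'   truth: cDNA/gDNA log2 measurement noise sd and cohort size.
#' @param calibration_slope,calibration_intercept,calibration_noise_sd
#'   forward model of the mixing-series standard curve.
#' @param eqtl_beta,eqtl_n,eqtl_noise_sd,maf eQTL cohort truth: slope per
#'   dosage unit, sample size, residual sd and minor allele frequency.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_bp = 1e6,
                       gc_fraction = 0.41,
                       n_planted_motifs = 200L,
                       n_case_snps = 100L,
                       n_control_snps = 100L,
                       fraction_snps_near_motif = 0.5,
                       near_distance_bp = 100L,
                       peak_width_mean_bp = 500L,
                       n_random_peaks = 200L,
                       ld_block_size = 4L,
                       proxy_r2_range = c(0.5, 1),
                       true_allelic_ratio = 1.3,
                       allelic_noise_sd = 0.1,
                       n_heterozygotes = 23L,
                       calibration_slope = 0.95,
                       calibration_intercept = 0.1,
                       calibration_noise_sd = 0.05,
                       eqtl_beta = 0.4,
                       eqtl_n = 500L,
                       eqtl_noise_sd = 1,
                       maf = 0.3) {
  cfg <- as.list(environment())
  stopifnot(cfg$genome_length_bp > 0,
            cfg$gc_fraction > 0, cfg$gc_fraction < 1,
            cfg$n_planted_motifs >= 0, cfg$n_case_snps >= 0,
            cfg$n_control_snps >= 0,
            cfg$fraction_snps_near_motif >= 0,
            cfg$fraction_snps_near_motif <= 1,
            cfg$near_distance_bp >= 0, cfg$peak_width_mean_bp > 0,
            cfg$ld_block_size >= 1,
            length(cfg$proxy_r2_range) == 2L,
            all(cfg$proxy_r2_range >= 0), all(cfg$proxy_r2_range <= 1),
            cfg$true_allelic_ratio > 0, cfg$allelic_noise_sd >= 0,
            cfg$n_heterozygotes >= 2, cfg$calibration_noise_sd >= 0,
            cfg$eqtl_n >= 3, cfg$eqtl_noise_sd >= 0)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with planted motif instances
#'
#' Draws i.i.d. bases at the requested GC fraction and overwrites
#' non-overlapping, uniformly placed windows with motif instances — by
#' default the consensus word; `plant_mode = "sample"` draws each planted
#' base from the matrix columns instead (instances then carry realistic
#' mismatches, and scan recovery depends on how sharp the matrix is).
#'
#' @param config a [sim_config()].
#' @param motif the [pwm()] to plant (default [ap1_pwm()]).
#' @param plant_mode `"consensus"` (default) or `"sample"`.
#' @return list with `sequences` (named character vector, one chromosome
#'   `chr1`), `motifs` (data.frame `chrom`, `start`, `end`, `instance` —
#'   0-based half-open planted windows).
#' @export
generate_genome <- function(config, motif = ap1_pwm(),
                            plant_mode = c("consensus", "sample")) {
  plant_mode <- match.arg(plant_mode)
  L <- as.integer(config$genome_length_bp)
  W <- motif$width
  n <- as.integer(config$n_planted_motifs)
  if (n > 0 && n > floor(L / (2 * W))) {
    stop("more planted motifs than fit in the genome")
  }
  gc <- config$gc_fraction
  withr::with_seed(config$seed + GENOME_SEED_OFFSET, {
    bases <- sample(BASES, L, replace = TRUE,
                    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    starts <- integer(0)
    if (n > 0) {
      cand <- sort(sample.int(L - W + 1L, min(L - W + 1L, n * 10L))) - 1L
      keep <- logical(length(cand))
      last_end <- -1L
      for (i in seq_along(cand)) {
        if (cand[i] > last_end) {
          keep[i] <- TRUE
          last_end <- cand[i] + W  # enforce a >= 1 bp gap between instances
        }
      }
      starts <- cand[keep]
      if (length(starts) < n) stop("could not place all planted motifs")
      starts <- sort(sample(starts, n))
    }
    instances <- character(length(starts))
    for (i in seq_along(starts)) {
      inst <- if (plant_mode == "consensus") {
        strsplit(pwm_consensus(motif), "")[[1]]
      } else {
        vapply(seq_len(W),
               function(j) sample(BASES, 1L, prob = motif$prob[, j]),
               character(1))
      }
      bases[(starts[i] + 1L):(starts[i] + W)] <- inst
      instances[i] <- paste(inst, collapse = "")
    }
  })
  list(
    sequences = c(chr1 = paste(bases, collapse = "")),
    motifs = data.frame(chrom = rep("chr1", length(starts)),
                        start = starts, end = starts + W,
                        instance = instances, stringsAsFactors = FALSE)
  )
}

#' Write simulated sequences as FASTA
#'
#' @param sequences named character vector (as in [generate_genome()]).
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Simulate case/control SNP panels with block LD structure
#'
#' A fraction of case SNPs is placed within `near_distance_bp` of planted
#' motif centers; the remainder, and all control SNPs, are uniform on the
#' genome. Case SNPs are grouped into consecutive blocks of
#' `ld_block_size`; the first SNP of each block is the lead, the second (if
#' any) is a perfect proxy (r2 = 1), and further proxies draw r2 from
#' `proxy_r2_range`. |D'| is drawn consistently with r2 <= D'^2.
#'
#' @param config a [sim_config()].
#' @param planted_motifs the `motifs` data.frame from [generate_genome()].
#' @return list with `case`, `control` (both [variant_table()]s carrying
#'   `maf` and logical `near_motif`), `leads` (the block leads), `ld` (an
#'   [ld_table()] data.frame) and `truth`.
#' @export
generate_snp_panel <- function(config, planted_motifs) {
  L <- as.integer(config$genome_length_bp)
  n_case <- as.integer(config$n_case_snps)
  n_ctrl <- as.integer(config$n_control_snps)
  withr::with_seed(config$seed + SNP_SEED_OFFSET, {
    n_near <- round(config$fraction_snps_near_motif * n_case)
    if (nrow(planted_motifs) == 0L) n_near <- 0L
    near_pos <- integer(0)
    if (n_near > 0) {
      centers <- floor((planted_motifs$start + planted_motifs$end) / 2)
      anchor <- sample(centers, n_near, replace = TRUE)
      off <- sample(seq(-config$near_distance_bp, config$near_distance_bp),
                    n_near, replace = TRUE)
      near_pos <- pmin(pmax(anchor + off, 0L), L - 1L)
    }
    far_pos <- sample.int(L, n_case - n_near) - 1L
    case_pos <- c(near_pos, far_pos)
    ctrl_pos <- sample.int(L, n_ctrl) - 1L

    case <- data.frame(
      rsid = sprintf("rs_case_%03d", seq_len(n_case)),
      chrom = rep("chr1", n_case), pos = case_pos,
      ref_allele = rep("A", n_case), alt_allele = rep("G", n_case),
      maf = rep(config$maf, n_case),
      near_motif = c(rep(TRUE, length(near_pos)),
                     rep(FALSE, n_case - length(near_pos))),
      stringsAsFactors = FALSE
    )
    control <- data.frame(
      rsid = sprintf("rs_ctrl_%03d", seq_len(n_ctrl)),
      chrom = rep("chr1", n_ctrl), pos = ctrl_pos,
      ref_allele = rep("A", n_ctrl), alt_allele = rep("G", n_ctrl),
      maf = rep(config$maf, n_ctrl), near_motif = rep(FALSE, n_ctrl),
      stringsAsFactors = FALSE
    )

    block <- ceiling(seq_len(n_case) / config$ld_block_size)
    is_lead <- !duplicated(block)
    ld_rows <- list()
    for (b in unique(block)) {
      members <- which(block == b)
      if (length(members) < 2L) next
      lead <- case$rsid[members[1L]]
      proxies <- case$rsid[members[-1L]]
      r2 <- c(1, if (length(proxies) > 1L)
        runif(length(proxies) - 1L, config$proxy_r2_range[1],
              config$proxy_r2_range[2]))
      dmin <- sqrt(r2)
      dprime <- dmin + runif(length(proxies)) * (1 - dmin)
      ld_rows[[length(ld_rows) + 1L]] <- data.frame(
        lead_rsid = lead, proxy_rsid = proxies, r2 = r2, dprime = dprime,
        population = "SIM", stringsAsFactors = FALSE)
    }
    ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else
      data.frame(lead_rsid = character(), proxy_rsid = character(),
                 r2 = numeric(), dprime = numeric(),
                 population = character(), stringsAsFactors = FALSE)
  })
  list(case = variant_table(case),
       control = variant_table(control),
       leads = variant_table(case[is_lead, , drop = FALSE]),
       ld = ld,
       truth = list(near_motif = setNames(case$near_motif, case$rsid),
                    block = setNames(block, case$rsid),
                    is_lead = setNames(is_lead, case$rsid)))
}

random_widths <- function(n, mean_bp) {
  pmax(100L, as.integer(round(rnorm(n, mean_bp, mean_bp / 4))))
}

make_jittered_peaks <- function(centers, widths, jitter_bp, L) {
  ctr <- centers + sample(seq(-jitter_bp, jitter_bp), length(centers),
                          replace = TRUE)
  start <- pmax(0L, as.integer(ctr - floor(widths / 2)))
  end <- pmin(L, start + widths)
  keep <- end > start
  data.frame(chrom = "chr1", start = start[keep], end = end[keep],
             score = stats::rlnorm(sum(keep), log(10), 0.5),
             stringsAsFactors = FALSE)
}

#' Simulate epigenomic peak sets over a genome with planted motifs
#'
#' Builds ATAC (open chromatin), H3K27ac (active enhancer) and TF-binding
#' peak sets as mixtures of motif-centered peaks (with positional jitter)
#' and uniformly placed background peaks, plus a DHS background universe
#' constructed as the merged superset of all three peak sets and additional
#' random intervals — so `ps_intersect(atac, dhs)` always returns all of
#' `atac`. With `motif_fraction = 0` every peak is placed uniformly and no
#' enrichment is planted (the null configuration).
#'
#' @param config a [sim_config()].
#' @param planted_motifs the `motifs` data.frame from [generate_genome()].
#' @param motif_fraction fraction of planted motifs that receive a peak in
#'   each peak set (default 0.8).
#' @return list of [peak_set()]s: `atac`, `h3k27ac`, `tf`, `dhs`.
#' @export
generate_peaks <- function(config, planted_motifs, motif_fraction = 0.8) {
  L <- as.integer(config$genome_length_bp)
  wmean <- config$peak_width_mean_bp
  n_rand <- as.integer(config$n_random_peaks)
  centers_all <- if (nrow(planted_motifs))
    floor((planted_motifs$start + planted_motifs$end) / 2) else integer(0)
  withr::with_seed(config$seed + PEAK_SEED_OFFSET, {
    one_set <- function(width_factor) {
      n_mot <- round(motif_fraction * length(centers_all))
      ctr_mot <- if (n_mot > 0) sample(centers_all, n_mot) else integer(0)
      ctr_rand <- sample.int(L, n_rand) - 1L
      ctr <- c(ctr_mot, ctr_rand)
      make_jittered_peaks(ctr, random_widths(length(ctr),
                                             wmean * width_factor),
                          jitter_bp = 50L, L = L)
    }
    atac_df <- one_set(1)
    k27_df <- one_set(2)
    tf_df <- one_set(0.6)
    extra <- make_jittered_peaks(sample.int(L, n_rand) - 1L,
                                 random_widths(n_rand, wmean),
                                 jitter_bp = 0L, L = L)
  })
  atac <- ps_merge(peak_set(atac_df, label = "atac"))
  k27 <- ps_merge(peak_set(k27_df, label = "h3k27ac"))
  tf <- ps_merge(peak_set(tf_df, label = "tf"))
  dhs_df <- rbind(atac$intervals[, c("chrom", "start", "end", "score")],
                  k27$intervals[, c("chrom", "start", "end", "score")],
                  tf$intervals[, c("chrom", "start", "end", "score")],
                  extra[, c("chrom", "start", "end", "score")])
  dhs <- ps_merge(peak_set(dhs_df, label = "dhs"))
  list(atac = atac, h3k27ac = k27, tf = tf, dhs = dhs)
}

#' Simulate a mixing-series calibration and heterozygote allelic data
#'
#' Calibration points follow the standard 8:1 .. 1:8 two-allele mixing
#' series through the linear forward model
#' `log2 intensity = slope * log2(mix) + intercept + noise`. Heterozygote
#' measurements are drawn with the configured true allelic ratio for cDNA
#' and a true ratio of 1 for gDNA, with independent Gaussian noise (sd
#' `allelic_noise_sd`) on each log2 measurement.
#'
#' @param config a [sim_config()].
#' @return list with `calibration` (data.frame `mix_ratio`,
#'   `log2_intensity_ratio`), `measurements` (data.frame `sample_id`,
#'   `locus`, `cdna_log2_ratio`, `gdna_log2_ratio`) and `truth`.
#' @export
generate_allelic_dataset <- function(config) {
  slope <- config$calibration_slope
  icpt <- config$calibration_intercept
  withr::with_seed(config$seed + ALLELIC_SEED_OFFSET, {
    mix <- c(8, 4, 2, 1, 0.5, 0.25, 0.125)
    calibration <- data.frame(
      mix_ratio = mix,
      log2_intensity_ratio = slope * log2(mix) + icpt +
        rnorm(length(mix), 0, config$calibration_noise_sd)
    )
    n <- as.integer(config$n_heterozygotes)
    measurements <- data.frame(
      sample_id = sprintf("het_%02d", seq_len(n)),
      locus = "rs_synthetic",
      cdna_log2_ratio = slope * log2(config$true_allelic_ratio) + icpt +
        rnorm(n, 0, config$allelic_noise_sd),
      gdna_log2_ratio = icpt + rnorm(n, 0, config$allelic_noise_sd),
      stringsAsFactors = FALSE
    )
  })
  list(calibration = calibration, measurements = measurements,
       truth = list(slope = slope, intercept = icpt,
                    allelic_ratio = config$true_allelic_ratio))
}

#' Simulate a genotype-expression cohort
#'
#' Genotypes are Hardy-Weinberg draws at the configured minor allele
#' frequency; expression is `beta * dosage + Gaussian noise`. Optionally a
#' second SNP is generated in LD with the first at a target r2 via
#' two-locus haplotype sampling (D = r q(1-q), equal allele frequencies), so
#' its realized dosage correlation matches the target in expectation.
#'
#' @param config a [sim_config()].
#' @param ld_r2 target squared correlation of an optional second SNP with
#'   the first (`NULL`, the default, simulates a single SNP).
#' @return a cohort list: `genotypes` (n x SNPs matrix), `expression`
#'   (n x 1 matrix, column `gene_1`), `snp_pos`, `gene_pos`, `truth`.
#' @export
generate_eqtl_cohort <- function(config, ld_r2 = NULL) {
  q <- config$maf
  if (!(q > 0 && q <= 0.5)) stop("maf must lie in (0, 0.5]")
  n <- as.integer(config$eqtl_n)
  beta <- config$eqtl_beta
  withr::with_seed(config$seed + EQTL_SEED_OFFSET, {
    if (is.null(ld_r2)) {
      g1 <- sample(0:2, n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
      genotypes <- cbind(rs_sim_1 = g1)
    } else {
      stopifnot(ld_r2 >= 0, ld_r2 <= 1)
      r <- sqrt(ld_r2)
      D <- r * q * (1 - q)
      hap_freq <- c(`11` = q^2 + D, `10` = q * (1 - q) - D,
                    `01` = q * (1 - q) - D, `00` = (1 - q)^2 + D)
      haps <- sample(names(hap_freq), 2L * n, replace = TRUE,
                     prob = hap_freq)
      a1 <- as.integer(substr(haps, 1, 1))
      a2 <- as.integer(substr(haps, 2, 2))
      g1 <- a1[seq_len(n)] + a1[n + seq_len(n)]
      g2 <- a2[seq_len(n)] + a2[n + seq_len(n)]
      genotypes <- cbind(rs_sim_1 = g1, rs_sim_2 = g2)
    }
    expression <- cbind(gene_1 = beta * genotypes[, "rs_sim_1"] +
                          rnorm(n, 0, config$eqtl_noise_sd))
  })
  list(
    genotypes = genotypes,
    expression = expression,
    snp_pos = data.frame(rsid = colnames(genotypes), chrom = "chr1",
                         pos = c(500000L, 500500L)[seq_len(ncol(genotypes))],
                         stringsAsFactors = FALSE),
    gene_pos = data.frame(gene = "gene_1", chrom = "chr1", pos = 510000L,
                          stringsAsFactors = FALSE),
    truth = list(beta = beta, maf = q, ld_r2 = ld_r2,
                 noise_sd = config$eqtl_noise_sd)
  )
}

#' Simulate a functional-annotation table consistent with planted truth
#'
#' Causal variants receive strong regulatory evidence (functional score 1-2,
#' several bound factors); all other variants receive weak evidence (score
#' 5-6 or no bound factor), so the funnel's annotation filter retains
#' exactly the causal set.
#'
#' @param rsids all variant identifiers to annotate.
#' @param causal_rsids subset that is truly regulatory.
#' @param seed integer seed.
#' @return data.frame `rsid`, `functional_score`, `n_bound_factors`.
#' @export
generate_annotations <- function(rsids, causal_rsids, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    causal <- rsids %in% causal_rsids
    data.frame(
      rsid = rsids,
      functional_score = ifelse(causal, sample(1:2, length(rsids), TRUE),
                                sample(5:6, length(rsids), TRUE)),
      n_bound_factors = ifelse(causal, sample(1:5, length(rsids), TRUE), 0L),
      stringsAsFactors = FALSE
    )
  })
}
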