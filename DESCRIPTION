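Package: regprior
Title: Prioritization of Regulatory GWAS Variants with Epigenomic Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing non-coding GWAS variants with cell-type
    epigenomic data: linkage-disequilibrium expansion of lead SNPs, peak-overlap
    enrichment against a DNaseI-hypersensitivity background (one-sided Fisher's
    exact test), cumulative-binomial open-chromatin enrichment, position weight
    matrix scanning with a column-permutation randomized-matrix null and a
    SNP-motif proximity test, super-enhancer stitching and rank-curve calling,
    allele-specific expression quantification with mixing-series calibration
    curves, and linear-model cis-eQTL association with conditional
    residual-regression analysis. A synthetic-data module generates genomes
    with planted motifs, enriched peak sets, LD-structured SNP panels, allelic
    intensity data and genotype-expression cohorts with known ground truth so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
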