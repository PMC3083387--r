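Package: annotBF
Title: Empirical Annotation Bayes Factors for GWAS SNP Prioritisation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-ranks genome-wide association study (GWAS) SNPs by posterior
    odds of true association, combining Wakefield approximate Bayes Factors
    computed from per-SNP effect estimates with annotation Bayes Factors
    estimated empirically as the ratio of annotation prevalence in GWAS hit
    sets versus genotyping-panel backgrounds. Supports direct and LD-proxy
    annotation transfer (r^2 thresholding), cis-eQTL and open-chromatin
    category construction, binomial enrichment tests with Bonferroni tiers,
    MAF stratification, hit-threshold sweeps, rank-change evaluation against
    random-set baselines, and a synthetic GWAS summary-statistic generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: GenomeWideAssociationStudies, SNP, Bayesian, FunctionalPrediction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
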