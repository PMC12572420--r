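Package: gibaxis
Title: Cross-Tissue Integration of GWAS Summary Statistics Along the
    Gut Microbiota-Immunity-Brain Axis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating genome-wide association study (GWAS)
    summary statistics across studies and tissues: inverse-variance
    fixed-effects meta-analysis with a DerSimonian-Laird random-effects
    fallback under a heterogeneity trigger, LD-clump based novel-locus
    screening against a known-locus database, gene-window annotation with
    polygenic priority scores (PoPS), hypergeometric over-representation of
    SNP sets in eQTL contexts and of gene lists in GMT gene sets with
    Benjamini-Hochberg control, summary-data-based Mendelian randomization
    (SMR) against eQTL/mQTL summaries, bidirectional two-sample Mendelian
    randomization (IVW, MR-Egger, weighted median, mode estimators,
    Cochran's Q, Egger intercept, MR-PRESSO global test, leave-one-out),
    and a cross-dimension intersection that nominates pleiotropic hub SNPs.
    A synthetic-data module simulates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    fgsea
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
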