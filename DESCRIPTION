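Package: pooledscan
Title: Pooled-DNA GWAS Allelotyping, Block-Based Candidate Selection and
    Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for case/control association discovery with pooled-DNA
    genome-wide association scans. Computes relative allele signal (RAS)
    from two-channel array intensities, screens pools for outliers with a
    principal-component quality control step, scans SNPs with Welch
    t-tests and Bonferroni correction, selects candidate loci as blocks
    of at least ten tightly spaced associated SNPs with stricter index
    SNPs, and validates candidates by individual genotyping with allelic
    Fisher exact tests, Woolf odds-ratio confidence intervals, a two-tier
    significance classification, and cross-disease shared-locus
    accounting. Includes a seedable synthetic cohort generator (LD-block
    haplotypes, seeded risk loci, pooling designs, array noise) so the
    whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
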