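Package: spastigen
Title: Case-Control GWAS Pipeline for Spastic Syndrome in Holstein Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for the genomic dissection of a binary
    late-onset disease (spastic syndrome) in pedigreed dairy cattle: a synthetic
    cohort generator (gene-dropping on a simulated half-sib pedigree with a
    liability-threshold disease architecture), PLINK text and minimal VCF input,
    pre-GWAS quality control (call rates, heterozygosity excess, minor allele
    frequency), pedigree additive-relationship and inbreeding computation,
    liability-scale heritability estimation by penalized quasi-likelihood with a
    probit link and the underlying/observed scale transformation, a
    kinship-aware generalized quasi-likelihood score (GQLS) association scan
    with chromosome-wise positive-FDR q-values, a post-GWAS filter cascade
    (MAF, genotype chi-square, homozygotic polarity score), a replicated
    class-balanced random-forest consensus scan with out-of-bag and test-set
    error reporting, two-locus EM linkage disequilibrium, solid-spine haplotype
    blocks, syntenic-LD screening, and SNP-to-gene window mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ranger,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    nlme,
    optparse
Config/testthat/edition: 3
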