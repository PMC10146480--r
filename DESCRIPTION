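Package: snpher
Title: SNP-Based Heritability of Late-Onset Disease by GREML-LDMS with
    Liability-Scale Conversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates SNP-based heritability of late-onset binary disease
    from individual-level genotypes with genome-based restricted maximum
    likelihood (GREML), including multi-component GREML-LDMS fits that
    stratify SNPs by segment-based LD score and minor allele frequency.
    Provides genetic relatedness matrix (GRM) construction with GCTA-format
    input/output, PLINK 1 binary genotype input/output, region and gene-set
    SNP filters, and conversion of observed-scale estimates to the liability
    scale under case-control ascertainment, with an age-aware uplift of the
    case proportion for cohorts whose controls are unscreened for a disease
    they may yet develop. A synthetic-cohort generator simulates
    age-structured liability-threshold cohorts with a major-effect locus,
    a polygenic background and a concentrated gene-set, so the full analysis
    can be exercised and calibrated without access to controlled genotype
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
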