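Package: cgcp
Title: Exhaustive Case-Exclusive Genotype Combination Search for Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines case-control SNP genotype data for causal genotype combination
    patterns (CGCPs): r-SNP genotype combinations carried by a minimum number of
    cases and by no control, whose prevalence-weighted population frequency lies
    inside bounds derived from the disease prevalence. Provides genotype matrix
    input/output in a simple TSV dialect (optionally minimal VCF), quality-control
    filtering by minor allele frequency and Hardy-Weinberg equilibrium, the
    exhaustive combination search with a brute-force oracle, a subsampling
    permutation test of carrier counts, the label-swapped (inverse) analysis,
    a seeded synthetic cohort generator with planted case-exclusive patterns,
    and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
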