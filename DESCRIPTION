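Package: snpreplicate
Title: Replication Assessment for Candidate-Gene SNP Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the reproducibility of published
    candidate-gene SNP associations in case-control studies of allergic
    rhinitis and similar phenotypes. Provides per-SNP association
    statistics (allele and genotype chi-square homogeneity tests,
    Hardy-Weinberg equilibrium checks, minor-allele odds ratios with
    confidence intervals, Kruskal-Wallis tests of quantitative skin-prick
    scores by genotype), Storey-style q-values and observed-versus-expected
    P-value bin tables, simulation-based power for the allele test given
    published odds ratios, the expected-significant-count statistic, and
    cross-study concordance of odds ratios (Spearman correlation and sign
    concordance). A synthetic cohort generator with Hardy-Weinberg
    genotypes under a multiplicative allelic odds model makes every stage
    testable without access to individual-level genotype data. Ships a
    catalog of 33 published associations as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
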