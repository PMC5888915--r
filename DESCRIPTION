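Package: mafdd
Title: Pooled-Sequencing BSA Mapping for F1 Crosses of Heterozygous Parents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked segregant analysis of pooled whole-genome sequencing data
    for F1 populations of out-crossing, highly heterozygous species. Implements
    mutant allele frequency and density (MAFD) mapping on mutant-pool-specific
    variants, and allele frequency directional difference and density (AFDDD)
    mapping on pool-common variants, with moving-window allele-frequency
    profiles, per-Mb variant density and z-score peak detection. Includes the
    pseudo-testcross segregation-type model (expected pool allele frequencies
    for <lm x mm>, <lm x ll> and <hk x hk> variants under linkage to a dominant
    causal locus), a two-stage variant filter cascade, genotype-group
    classification of pool-common variants, chi-square segregation tests, and a
    Mendelian F1 cross-and-pooling simulator used as the test harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    tools,
    utils,
    vcfR,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
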