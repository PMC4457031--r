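Package: f2map
Title: Recessive-Trait Mapping and Digital Expression Analysis in F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping a fully penetrant autosomal-recessive locus in a
    two-founder F2 intercross and characterizing its downstream consequences.
    Provides founder-origin inference and a per-marker association scan with
    Bonferroni control, shared-homozygosity (identity-by-descent) interval
    detection with recombination-breakpoint refinement, a Mendelian
    variant-exclusion cascade with population screening, in-silico PCR-RFLP and
    truncation prediction, exact Poisson-based two-library differential
    expression (RPKM, equal-expression test, FDR), rank-list consensus gene
    prioritization, and a human coding-variant filter. Every input can be
    simulated with known planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
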