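Package: pedimpute
Title: Pedigree-Aware Genotype Imputation and Its Evaluation in Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build, run and evaluate low-density-to-sequence genotype
    imputation in pedigreed breeding populations. Includes a gene-dropping
    simulator that emulates a two-mating-set breeding design with a dense
    sequence panel and a sparse SNP chip, the post-calling variant filter
    cascade (quality, monomorphism, dual-caller concordance, Mendelian
    segregation), a pluggable imputer interface with a frequency random-fill
    lower bound and a windowed family/LD imputer, leave-one-out masking
    cross-validation with per-individual and per-SNP concordance metrics
    (including a chance-corrected proportion), per-SNP explanatory factors
    (minor allele frequency, exact Hardy-Weinberg test, depth, quality,
    chip/sequence density ratio), Lewontin's D' linkage-disequilibrium
    profiling, and gene-model-based annotation profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    Biostrings,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
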