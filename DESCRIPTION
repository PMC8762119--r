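Package: impsim
Title: Simulation-Based Evaluation of Genotype Imputation Accuracy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genotype imputation accuracy by simulation in
    structured livestock populations. Simulates phased sequence-resolution
    haplotypes under a multi-population coalescent with recombination,
    migration and population splits; ascertains SNP-chip-like (evenly spaced)
    and low-coverage-sequencing-like (random) marker panels at chosen
    densities; imputes masked variants with a Li-Stephens haplotype-copying
    hidden Markov model (with adapters for external imputation tools); and
    scores imputation by per-locus reliability (squared correlation) and
    allelic error rate, with minor-allele-frequency binning, factorial
    experiment orchestration, coefficient-of-variation factor ranking and
    genomic kinship summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
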