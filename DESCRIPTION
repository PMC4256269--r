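Package: mksweep
Title: Suppressor Sweeps Against Male-Killing Wolbachia: Models, Drift
    Nulls and Sweep Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the spread of a dominant zygotic suppressor
    of Wolbachia-induced male killing through a host population, modelled on
    the episode observed in the butterfly Hypolimnas bolina.  Provides a
    deterministic multi-locus recursion for the selective sweep (with
    cytoplasmic incompatibility and male-limited recombination), Wright-
    Fisher drift null models including the Kimura diffusion probability of
    allele loss, sweep-detection statistics for pre/post-sweep haplotype
    samples (G-test heterogeneity with standardized-residual identification
    of swept alleles, F_ST, effective allele number, nucleotide diversity,
    linkage-disequilibrium significance, sequential Bonferroni), linkage
    analysis of informative crosses exploiting achiasmatic female meiosis,
    and a seeded synthetic-data generator for all pipeline inputs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
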