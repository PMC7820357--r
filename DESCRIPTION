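Package: mutacc
Title: Mutation Rates, Spectra, and Gene Conversion from
    Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of mutation-accumulation (MA) sequencing experiments in
    diploid, clonally propagated organisms such as Daphnia. Detects de novo
    nuclear base substitutions, mitochondrial heteroplasmies, and
    gene-conversion (loss-of-heterozygosity) tracts from ancestor/descendant
    genotype call sets; estimates per-generation mutation and conversion rates
    with bootstrap confidence intervals at line, genotype, population, and
    species level; computes six-class and trinucleotide-context mutation
    spectra, Ts:Tv ratios and CpG contrasts; and derives equilibrium GC
    content, expected heterozygosity, effective population size, and
    quantitative-genetic summaries of the mutation rate as a trait. Includes
    a forward simulator of MA experiments (Poisson nuclear mutation with a
    configurable spectrum, geometric gene-conversion tracts, Wright-Fisher
    mitochondrial copy-number drift) with a complete ground-truth ledger for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
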