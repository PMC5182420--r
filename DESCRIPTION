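Package: rohmap
Title: Autozygosity Mapping of Recessive Traits from Homozygosity Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps fully penetrant recessive traits in closed breeding
    populations. Computes per-marker observed heterozygosity in an affected
    cohort and extracts, tallies and ranks maximal runs of contiguous
    fully-homozygous SNPs; filters a multi-sample VCF for variants
    homozygous in a sequenced case and absent from a control panel;
    intersects candidates with the mapped region and classifies coding
    consequences including frameshift protein arithmetic and HGVS p.
    notation. Includes a pedigree gene-drop simulator (Haldane
    recombination, founder haplotypes, planted private frameshift) that
    provides ground-truthed synthetic studies, and a deterministic
    genotype-to-pelage rule engine for the five canine coat genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    ggplot2,
    methods,
    rlang,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
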