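Package: nanochromkit
Title: Nanochromosome Genome Analysis Toolkit
Version: 0.1.0
Authors@R: person("Macronuclear", "Genomics Lab", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for ciliate macronuclear genomes built from
    gene-sized, telomere-capped nanochromosomes. Provides telomere
    detection/masking and telomere-class assembly statistics, telomere-aware
    contig finishing (end extension, greedy overlap merging, chimera
    splitting from unspanned paired-end intervals), a minimal seeded read
    mapper, pileup-based variant calling with homozygous/heterozygous
    nanochromosome classification and effective-population-size estimation
    from four-fold synonymous diversity, telomere-addition-site calling with
    alternative-fragmentation detection and isoform prediction, read-depth
    and telomeric-read copy-number estimation with one-sided
    Kolmogorov-Smirnov group comparisons, and a seeded synthetic
    nanochromosome genome and read simulator with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer
Config/testthat/edition: 3
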