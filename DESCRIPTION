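Package: genarch
Title: Comparative Genome Architecture of Selfing and Outcrossing Nematodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome architecture between related species
    that differ in mating system, motivated by the repeated evolution of
    self-fertilisation in Caenorhabditis nematodes. Provides interval-based
    footprint accounting of exonic, intronic, intergenic and repeat content;
    nonparametric comparisons of intergenic spacing, gene size and protein
    size between chromosome classes (X versus autosomes) and between species;
    synteny-block construction from ortholog position tables with
    translocation filtering, chromosome-retention estimates, divergent-region
    scans and indel size-bias tests; a two-pass k-mer spectrum read filter
    for assembly preprocessing; a GC/coverage scaffold contamination
    classifier; residual-polymorphism estimation partitioned by genomic
    feature class; and segregation-distortion quality control for
    recombinant-inbred-line markers. A synthetic multi-species genome
    generator with known ground truth supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    S4Vectors,
    Biostrings,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
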