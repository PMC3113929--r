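Package: tillploid
Title: TILLING Mutation Screens in Allotetraploid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of TILLING (Targeting Induced Local
    Lesions IN Genomes) reverse-genetics screens in allotetraploid species,
    where every target gene is present as a homeologous pair. Provides gene
    models with ATG-anchored coordinate maps, an EMS M2 population simulator
    with Mendelian 1:2:1 transmission, homeolog-specific nested in-silico PCR,
    CEL1 heteroduplex-cleavage screening with dual-channel fragment detection,
    four-fold pool deconvolution and zygosity calling, mutation-effect
    annotation with codon bookkeeping and epitope overlap, degenerate
    restriction-site mapping with CAPS marker design and Southern
    fragment-count prediction, and edge-corrected mutation-density (kb/SNP)
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, Sequencing, Software
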