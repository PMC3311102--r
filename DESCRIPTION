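Package: haplomosaic
Title: Comparative Haplotype Mosaic Analysis for Panels of Collinear Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis engine for comparing many collinear genomes from a
    biallelic SNP panel of inbred strains. Discovers recombination-free
    compatible intervals with the four-gamete test (maximal-k scan, minimal
    full covering), partitions strains into haplotype groups per interval,
    computes dynamic identity-by-descent over strain subsets, assigns
    transition-minimizing haplotype mosaic colorings with order-based
    recoloring and position-radiating sorting, infers subspecific-origin and
    heterozygosity mosaics with Viterbi hidden Markov models over diagnostic
    SNPs, builds local neighbor-joining phylogenies per interval, and renders
    scale-adaptive static genome track images (SVG/PNG). Includes a
    ground-truthed founder-mosaic panel simulator and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
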