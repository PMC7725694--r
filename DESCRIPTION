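Package: mhcfkit
Title: Allele Discovery and Molecular Evolution of Primate MHC-F
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genetics toolkit for the nonclassical MHC class I
    gene F (HLA-F and its nonhuman-primate orthologues). Simulates species
    cohorts with realistic allele repertoires, pedigrees, bone-marrow
    chimerism, barcoded replicate amplicon reads, heterozygous Sanger
    consensus data and alternative-splice isoforms; calls alleles from
    demultiplexed replicate reads with a two-independent-PCR confirmation
    rule and chimera rejection; resolves heterozygous IUPAC consensus
    sequences against homozygotes and pedigree-shared alleles; annotates
    indels, splice isoforms and pseudogene-inactivating lesions; builds
    neighbor-joining trees with bootstrap support, assigns nomenclature
    lineages, and computes Nei-Gojobori dN/dS with Jukes-Cantor correction
    and codon-bootstrap standard errors over exon partitions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    optparse
Config/testthat/edition: 3
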