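Package: ctdnatools
Title: Phasing and Evolutionary Analysis of a Cellular T-DNA Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a single cellular T-DNA (cT-DNA) locus in
    a diploid, outcrossing plant host: recruits short reads homologous to a
    reference locus, separates them into per-accession haplotype alleles,
    catalogs indels with left-aligned positions and plant-insert and
    target-site-duplication classification, reconstructs the pre-insertion
    site from an empty-site genome, dates the insertion from the divergence
    of the locus' terminal inverted repeats, and maps allele pairs onto a
    neighbor-joining tree with indel-marker group assignment. Includes a
    seeded population simulator that emulates the evolutionary structure of
    such a locus (two allele clades, diploid accessions with cross-clade
    allele pairs, an inverted-center rearranged lineage, and error-bearing
    short reads) with machine-readable truth tables, so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
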