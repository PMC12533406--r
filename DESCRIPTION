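Package: colhelix
Title: Genetic-Algorithm Design of Heterotrimeric Collagen-Mimetic Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine for collagen-mimetic peptide (CMP) heterotrimers.
    Evolves sets of two or three Gly-periodic peptide strands toward
    self-assembly into a single target triple helix (A2B or ABC type) with a
    user-specified melting temperature and specificity, using an elitist
    genetic algorithm whose fitness is an additive, parameter-table-driven
    melting-temperature model evaluated over every competing composition and
    register. Supports conservation of biologically relevant motifs (such as
    the integrin-binding GFOGER sequence) on a chosen strand, exclusion of
    residues at Xaa/Yaa positions, FASTA input/output with the
    hydroxyproline code "O", and full competing-species audit reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
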