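Package: cycloscan
Title: Annotation and Taxonomy of Circular Rep-Encoding ssDNA (CRESS) Virus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to characterize small circular Rep-encoding single-stranded
    DNA (CRESS DNA) virus genomes, with an emphasis on cycloviruses. Locates
    the conserved nonanucleotide motif and its stem-loop at the origin of
    rolling-circle replication, rotates genomes to the ICTV position-one
    convention, enumerates open reading frames on both strands of the circular
    genome under multiple genetic codes and alternative initiation codons,
    reconstructs intron-split Rep coding sequences across canonical GT/AG
    splice sites, scans Rep proteins for rolling-circle replication and
    superfamily 3 helicase motifs, scores the arginine-rich capsid amino
    terminus, computes pairwise identity matrices by global alignment, applies
    ICTV genus and species demarcation thresholds, and builds neighbor-joining
    trees. A synthetic-genome simulator with full ground truth makes every
    stage testable without external sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
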