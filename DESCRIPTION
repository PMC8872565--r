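Package: trgkit
Title: Annotation and Comparative Analysis of T-Cell Receptor Gamma Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of T-cell receptor gamma (TRG) loci that are
    organized as tandemly duplicated V-J-(J)-C cassettes, as found in
    cetartiodactyl genomes. Annotates V, J and C genes from recombination
    signal (RS) sequences, splice sites and reference exons; classifies gene
    functionality into the IMGT-style F/ORF/P categories; groups V genes into
    subgroups at the 75 percent nucleotide-identity threshold; reveals the
    duplication architecture of a locus by dot-plot self-alignment and locates
    the PJ promoter and En enhancer elements with their STAT motifs;
    reconstructs neighbor-joining phylogenies from p-distances with bootstrap
    supports and converts them into calibrated timetrees by a relative-rate
    method; and assigns rearranged V-J-C cDNAs to their germline genes to
    quantify intra-cassette rearrangement preference. A synthetic-locus
    generator with full ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    seqinr,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
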