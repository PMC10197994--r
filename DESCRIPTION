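Package: cdpkfam
Title: Genome-Wide Survey of Calcium-Dependent Protein Kinase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide surveys of the
    calcium-dependent protein kinase (CDPK) gene family in plant genomes,
    built around the allotetraploid white clover (Trifolium repens) family.
    Family members are identified by reference-query local alignment plus a
    mandatory dual-domain (protein kinase + EF-hand) filter; members are
    placed in groups I-IV by neighbor-joining phylogeny with bootstrap
    support; conserved motifs are discovered by expectation-maximisation;
    duplicated genes are classified as tandem or segmental; a reference
    co-functional network is projected onto the target species via
    reciprocal best hits; network partners are tested for GO term
    enrichment with an elim-style hierarchy correction; and cold-stress
    time-course expression responses are called from RNA-seq counts and
    quantified from qPCR Ct tables by the 2^-ddCt method. Seeded synthetic
    data generators emit every input with a manifest of planted truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
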