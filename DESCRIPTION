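Package: cdr3shm
Title: Intraclonal CDR3 Somatic Hypermutation Profiling for Immunoglobulin Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of somatic hypermutation confined to the
    heavy-chain CDR3 of clonally expanded B-cell receptor rearrangements whose
    V gene is fully germline across FR1-FR3 ('truly unmutated' clones, as seen
    in stereotyped chronic lymphocytic leukemia subsets). Provides a paired-end
    amplicon repertoire simulator with injected subclonal variants and a truth
    ledger, read merging and CDR3-window quality control, a simplified gap-free
    V(D)J annotator with per-codon region provenance, clonotype and
    subclonal-variant calling with a read-count cutoff, per-position CDR3
    substitution profiling with rank-based positional-targeting statistics, and
    AID hotspot (WRC/GYW/WGCW) topology classification including
    junction-created hotspots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
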