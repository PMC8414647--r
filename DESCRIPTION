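Package: repscope
Title: Antibody Heavy-Chain Repertoire Analysis Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis of antibody heavy-chain (IGH) repertoire
    sequencing data. Reads clone tables in AIRR Rearrangement TSV, a MiXCR
    export subset, or a native TSV dialect, together with germline V/D/J/C
    segments in FASTA plus a region-boundary configuration. Clusters aligned
    records into clones by V/J(/C) gene and CDR3 nucleotide identity, extracts
    repertoire features (gene usage, CDR3 length distributions, junction
    insertion/deletion profiles, clonal diversity via Shannon, Simpson and
    D50), profiles somatic hypermutation with position-weighted matrices,
    silent/replacement/composite locus classification and hotspot/coldspot
    motif rates, compares experimental groups against reference repertoires,
    detects public (convergent) clones, annotates clones against an antibody
    database by exact CDR3 amino-acid identity with hypergeometric disease
    enrichment (Benjamini-Hochberg corrected), and serves near-exact
    nucleotide and exact amino-acid sequence queries. A seeded V(D)J
    recombination simulator with motif-biased hypermutation and power-law
    clonal expansion provides ground-truth fixtures for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
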