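Package: apaMiR
Title: Positional Enrichment of miRNA Seed-Match Sites Around Alternative
    Polyadenylation Sites
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for calling poly(A) cleavage sites from 3'-end
    sequencing read positions (read-run clustering, local-maxima site calling,
    internal-priming artifact filtering), assigning cleavage sites to 3'UTR
    models to identify genes with alternative polyadenylation (APA), scanning
    3'UTRs for perfect 7-mer miRNA seed-match sites, and testing whether
    conserved seed-match sites are positionally enriched immediately 5' of APA
    sites. Statistical machinery includes a randomized-APA null model,
    gene-set partition and cluster-versus-all permutation tests, score-window
    comparisons (P_CT / context-style site scores), per-base conservation
    profiles around anchors, and codon-usage based gene-set expansion. A
    synthetic-data generator emits every input format the pipeline consumes,
    with ground-truth bookkeeping for recovery and calibration studies.
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
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Transcriptomics, Sequencing, Software
Config/testthat/edition: 3
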