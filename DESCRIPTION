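Package: virotide
Title: Viral Community Dynamics Across a Macroalgal Bloom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-series viral metagenomics of coastal bloom
    systems. Implements the analysis chain from assembled contigs to
    ecological summaries: rule-based viral contig identification from
    per-tool score tables, greedy dereplication of viral contigs into
    viral operational taxonomic units (vOTUs) at 95% nucleotide identity
    over 80% of the shorter sequence, transcripts-per-million (TPM)
    abundance normalization, alpha diversity, classification of temporal
    abundance profiles into a single/wide/several peak typology,
    constrained and unconstrained ordination against environmental
    variables, integration of homology, tRNA and CRISPR-spacer evidence
    into virus-host linkages, auxiliary metabolic gene (AMG) abundance
    aggregation, hypergeometric gene-sharing networks and thresholded
    co-occurrence networks. A synthetic scenario generator with planted
    ground truth makes every stage testable end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
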