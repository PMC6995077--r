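Package: peakscreen
Title: Design and Analysis of Peak-Targeting CRISPR Screens for
    Noncoding Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design pooled CRISPR libraries against
    transcription-factor ChIP-Seq peaks and to analyze the resulting
    screens. Design scans peaks for degenerate dyad motifs with a
    variable-length spacer (e.g. the p53 consensus CWWG[N]{2,12}CWWG),
    enumerates every PAM-proximal sgRNA around each motif, removes guides
    with tolerated (CFD = 1) off-target sites in protein-coding genes or
    at multiple unrelated noncoding loci, and adds intergenic-targeting
    and non-targeting controls. Analysis converts sequencing reads or
    count tables into guide- and peak-level enrichment and depletion
    calls: median-ratio normalization, log2 fold changes relative to the
    plasmid DNA library, control-anchored empirical p-values,
    Benjamini-Hochberg FDR, median aggregation per peak, and
    distance-to-TSS annotation. A synthetic-data generator produces
    genomes, peaks, libraries and negative-binomial screen counts with
    known ground truth so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
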