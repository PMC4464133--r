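Package: rempscan
Title: Operon Association, Codon-Level Selection and Consensus Motifs for
    Redox Enzyme Maturation Protein Chaperones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying NarJ-subfamily redox enzyme maturation
    protein (REMP) chaperones and their cognate complex iron-sulfur
    molybdoenzyme (CISM) operons. Reads annotated genomes (GFF3 or TSV),
    extracts ORF-count gene neighborhoods, segments contigs into operons,
    classifies chaperone loci as cis, trans or absent relative to their
    cognate enzyme operons, and computes the frequency-of-gene-occurrence
    statistic together with presence/absence phi correlations. Threads
    coding sequences onto a protein multiple sequence alignment and
    computes pairwise Nei-Gojobori dN/dS with Jukes-Cantor correction,
    per-codon synonymous-substitution profiles and per-group percentile
    summaries. Extracts tiered consensus motifs numbered against a
    reference sequence. Ships a synthetic-genome and codon-evolution
    generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
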