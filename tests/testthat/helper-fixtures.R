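# Small fixture builders used across the suite.

# Annotation tibble for one contig: genes laid end to end with fixed gaps.
contig_tbl <- function(symbols, strand = "+", gap = 20, genome = "G1",
                       contig = "c1", start = 100, len = 300,
                       locus_prefix = "L", products = NULL) {
  n <- length(symbols)
  if (length(strand) == 1) strand <- rep(strand, n)
  if (length(gap) == 1) gap <- rep(gap, n - 1)
  if (is.null(products)) {
    products <- ifelse(symbols == "", "hypothetical protein",
      paste(symbols, "protein")
    )
  }
  starts <- integer(n)
  pos <- start
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + len + if (i < n) gap[i] else 0
  }
  as_annotation(tibble::tibble(
    genome_id = genome,
    contig_id = contig,
    locus_tag = sprintf("%s%s_%03d", locus_prefix, genome, seq_len(n)),
    gene_name = symbols,
    product = products,
    start = starts,
    end = starts + len - 1L,
    strand = strand
  ))
}

# Codon alignment for named codon vectors (no gaps).
aln_from_codons <- function(...) {
  seqs <- list(...)
  code <- genetic_code()
  msa <- vapply(seqs, function(cd) paste(unname(code[cd]), collapse = ""), character(1))
  cds <- vapply(seqs, function(cd) paste(cd, collapse = ""), character(1))
  thread_codons(msa, cds)
}

# Column contract of the canonical annotation table.
ANNOTATION_COLS_FOR_TEST <- function() {
  c(
    "genome_id", "contig_id", "locus_tag", "gene_name", "product",
    "start", "end", "strand", "rank"
  )
}

# A template with a single chaperone layout, for round-trip tests.
single_layout_template <- function(..., phylum = "TestPhylum") {
  genome_template(phylum = phylum, layouts = list(operon_layout(...)))
}
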