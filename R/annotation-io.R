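# Reading/writing genome annotations, sequences and alignments.
#
# Coordinates are 1-based inclusive everywhere (GFF3 convention). The
# canonical annotation table is a tibble sorted by (contig_id, start) with a
# 0-based per-contig `rank` column; parsing is order-insensitive because the
# sort is applied on read.

ANNOTATION_COLS <- c(
  "genome_id", "contig_id", "locus_tag", "gene_name", "product",
  "start", "end", "strand", "rank"
)

#' Read a genome annotation table
#'
#' Parses CDS annotations from GFF3 (via rtracklayer) or from a simple TSV
#' dialect with the header
#' `genome_id contig_id locus_tag gene_name product start end strand`.
#' The result is canonical: sorted by contig and start, with consecutive
#' 0-based ranks per contig and lower-cased gene symbols. Row order of the
#' input is irrelevant.
#'
#' @param path Path to a GFF3 or TSV file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @param genome_id Genome identifier to stamp on the records; for GFF3 it
#'   defaults to the file name without extension, for TSV to the value in the
#'   file.
#' @return A tibble with columns `genome_id, contig_id, locus_tag, gene_name,
#'   product, start, end, strand, rank`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "tsv"), genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path))
  }
  if (dialect == "gff3") {
    gff <- as.data.frame(rtracklayer::readGFF(path, filter = list(type = "CDS")))
    if (is.null(genome_id)) {
      genome_id <- sub("\\.[^.]*$", "", basename(path))
    }
    grab <- function(col) {
      if (col %in% names(gff)) as.character(gff[[col]]) else rep(NA_character_, nrow(gff))
    }
    tbl <- tibble(
      genome_id = genome_id,
      contig_id = as.character(gff$seqid),
      locus_tag = grab("locus_tag"),
      gene_name = grab("gene"),
      product = grab("product"),
      start = as.integer(gff$start),
      end = as.integer(gff$end),
      strand = as.character(gff$strand)
    )
    if (anyNA(tbl$locus_tag)) {
      abort(paste0(
        "GFF3 CDS feature(s) without a locus_tag attribute in ", path,
        " (rows ", paste(which(is.na(tbl$locus_tag)), collapse = ", "), ")"
      ))
    }
  } else {
    tbl <- readr::read_tsv(
      path,
      col_types = readr::cols(
        genome_id = readr::col_character(),
        contig_id = readr::col_character(),
        locus_tag = readr::col_character(),
        gene_name = readr::col_character(),
        product = readr::col_character(),
        start = readr::col_integer(),
        end = readr::col_integer(),
        strand = readr::col_character()
      ),
      progress = FALSE
    )
    probs <- readr::problems(tbl)
    if (nrow(probs) > 0) {
      abort(paste0(
        "malformed TSV annotation ", path, ": parse failure at line ",
        probs$row[1], " (", probs$expected[1], ")"
      ))
    }
    if (!is.null(genome_id)) tbl$genome_id <- genome_id
  }
  as_annotation(tbl)
}

#' Coerce and validate a data frame of gene records
#'
#' Applies the canonical form used by every downstream function: lower-cased
#' gene symbols, `NA`-safe products, a sort by `(contig_id, start)` and a
#' consecutive 0-based `rank` per contig. Validates the GFF3-style invariants
#' (1-based coordinates, `end >= start`, strands in `+/-`, locus tags unique
#' within a genome).
#'
#' @param tbl Data frame with at least `genome_id, contig_id, locus_tag,
#'   gene_name, product, start, end, strand`.
#' @return The canonical annotation tibble.
#' @export
as_annotation <- function(tbl) {
  need <- setdiff(ANNOTATION_COLS, c(names(tbl), "rank"))
  if (length(need)) {
    abort(paste0("annotation table missing column(s): ", paste(need, collapse = ", ")))
  }
  tbl <- as_tibble(tbl)
  tbl$gene_name <- tolower(dplyr::coalesce(as.character(tbl$gene_name), ""))
  tbl$product <- dplyr::coalesce(as.character(tbl$product), "")
  tbl$start <- as.integer(tbl$start)
  tbl$end <- as.integer(tbl$end)
  bad <- which(is.na(tbl$start) | is.na(tbl$end) | tbl$start < 1L | tbl$end < tbl$start)
  if (length(bad)) {
    abort(paste0(
      "invalid coordinates (need 1 <= start <= end) for locus_tag ",
      paste(tbl$locus_tag[bad], collapse = ", ")
    ))
  }
  if (!all(tbl$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-' for every record")
  }
  dup <- tbl %>%
    dplyr::count(.data$genome_id, .data$locus_tag) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0(
      "duplicate locus_tag within genome: ",
      paste(dup$locus_tag, collapse = ", ")
    ))
  }
  tbl %>%
    arrange(.data$genome_id, .data$contig_id, .data$start) %>%
    group_by(.data$genome_id, .data$contig_id) %>%
    mutate(rank = row_number() - 1L) %>%
    ungroup() %>%
    select(dplyr::all_of(ANNOTATION_COLS))
}

#' Write an annotation table
#'
#' Writes either the package TSV dialect or minimal GFF3 (CDS features with
#' `locus_tag`, `gene` and `product` attributes). Reading the file back with
#' [read_annotation()] reproduces the table.
#'
#' @param tbl Canonical annotation tibble.
#' @param path Output path.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param contig_lengths Optional named integer vector used for the GFF3
#'   `##sequence-region` pragmas; defaults to the max end per contig.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(tbl, path, dialect = c("tsv", "gff3"),
                             contig_lengths = NULL) {
  dialect <- match.arg(dialect)
  tbl <- as_annotation(tbl)
  if (dialect == "tsv") {
    readr::write_tsv(select(tbl, -"rank"), path, progress = FALSE)
  } else {
    esc <- function(x) {
      x <- gsub("%", "%25", x, fixed = TRUE)
      x <- gsub(";", "%3B", x, fixed = TRUE)
      x <- gsub("=", "%3D", x, fixed = TRUE)
      gsub(",", "%2C", x, fixed = TRUE)
    }
    if (is.null(contig_lengths)) {
      contig_lengths <- tapply(tbl$end, tbl$contig_id, max)
    }
    lines <- c(
      "##gff-version 3",
      paste("##sequence-region", names(contig_lengths), 1L, as.integer(contig_lengths))
    )
    attrs <- paste0(
      "ID=cds-", esc(tbl$locus_tag),
      ";locus_tag=", esc(tbl$locus_tag),
      ifelse(tbl$gene_name == "", "", paste0(";gene=", esc(tbl$gene_name))),
      ";product=", esc(tbl$product)
    )
    lines <- c(lines, paste(
      tbl$contig_id, "rempscan", "CDS", tbl$start, tbl$end, ".",
      tbl$strand, "0", attrs,
      sep = "\t"
    ))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a protein multiple sequence alignment from aligned FASTA
#'
#' @param path Aligned FASTA file; all sequences must have the same length.
#' @return Named character vector of aligned sequences (one string per id).
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  if (length(unique(nchar(seqs))) > 1) {
    abort(paste0(
      "ragged alignment in ", path, ": sequence lengths ",
      paste(unique(nchar(seqs)), collapse = ", ")
    ))
  }
  seqs
}

#' Read unaligned coding sequences from FASTA
#'
#' @param path Nucleotide FASTA file.
#' @param ids Optional identifiers that must all be present; an error names
#'   any missing one.
#' @return Named character vector of CDS nucleotide sequences.
#' @export
read_cds <- function(path, ids = NULL) {
  dna <- Biostrings::readDNAStringSet(path)
  seqs <- setNames(toupper(as.character(dna)), sub("\\s.*$", "", names(dna)))
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(seqs))
    if (length(missing)) {
      abort(paste0(
        "CDS file ", path, " is missing id(s): ", paste(missing, collapse = ", ")
      ))
    }
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Write a report table as TSV or JSON
#'
#' Reports round-trip losslessly through [read_report()].
#'
#' @param tbl A data frame (list columns are not supported in TSV).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(tbl, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    drop <- vapply(tbl, is.list, logical(1))
    readr::write_tsv(tbl[!drop], path, progress = FALSE)
  } else {
    jsonlite::write_json(tbl, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    as_tibble(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
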