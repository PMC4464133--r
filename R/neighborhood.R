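# ORF-count neighborhoods and same-strand operon segmentation.

#' Extract the ORF-count neighborhood of a locus
#'
#' Collects up to `radius` genes on each side of the focal locus, counted by
#' rank (gene index) on the same contig; strand and base-pair distance play
#' no role, and the window is truncated at contig ends. This mirrors a
#' "+/- 10 ORF radius" survey around a chaperone gene.
#'
#' @param tbl Canonical annotation tibble (see [as_annotation()]).
#' @param locus_tag Focal locus tag; must exist in `tbl`.
#' @param radius Number of genes on each side (default 10).
#' @return A tibble of the focal gene and its neighbors with extra columns
#'   `focal_locus_tag`, `side` (`upstream`/`focal`/`downstream`) and `offset`
#'   (signed rank difference from the focal gene). Rows are ordered by rank.
#' @export
extract_neighborhood <- function(tbl, locus_tag, radius = 10) {
  stopifnot(radius >= 1)
  hit <- tbl[tbl$locus_tag == locus_tag, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(paste0("locus_tag not found: ", locus_tag))
  }
  hit <- hit[1, ]
  focal_tag <- locus_tag
  tbl %>%
    filter(
      .data$genome_id == hit$genome_id,
      .data$contig_id == hit$contig_id,
      abs(.data$rank - hit$rank) <= radius
    ) %>%
    mutate(
      focal_locus_tag = focal_tag,
      offset = .data$rank - hit$rank,
      side = case_when(
        .data$offset < 0 ~ "upstream",
        .data$offset == 0 ~ "focal",
        TRUE ~ "downstream"
      )
    ) %>%
    arrange(.data$rank)
}

#' Extract neighborhoods for many loci at once
#'
#' @param tbl Canonical annotation tibble (may hold several genomes).
#' @param locus_tags Character vector of focal loci.
#' @inheritParams extract_neighborhood
#' @return Row-bound neighborhoods distinguished by `focal_locus_tag`.
#' @export
extract_neighborhoods <- function(tbl, locus_tags, radius = 10) {
  purrr::map_dfr(locus_tags, function(lt) extract_neighborhood(tbl, lt, radius))
}

#' Assign genes to operons
#'
#' Segments each contig into maximal runs of same-strand genes whose
#' successive intergenic gaps are at most `max_gap` base pairs. Every gene
#' belongs to exactly one operon; isolated genes form singleton operons. The
#' rule is the standard distance heuristic for prokaryotic operon calling and
#' stands in for manual inspection of operon annotations.
#'
#' @param tbl Canonical annotation tibble.
#' @param max_gap Maximum intergenic gap in bp within one operon (default 150).
#' @return `tbl` with an added `operon_id` column
#'   (`"<genome>:<contig>:<index>"`).
#' @export
assign_operons <- function(tbl, max_gap = 150) {
  tbl %>%
    arrange(.data$genome_id, .data$contig_id, .data$start) %>%
    group_by(.data$genome_id, .data$contig_id) %>%
    mutate(
      gap = .data$start - dplyr::lag(.data$end) - 1L,
      new_block = is.na(.data$gap) |
        .data$gap > max_gap |
        .data$strand != dplyr::lag(.data$strand),
      operon_id = paste(.data$genome_id, .data$contig_id, cumsum(.data$new_block), sep = ":")
    ) %>%
    ungroup() %>%
    select(-"gap", -"new_block")
}

#' Summarise operon calls
#'
#' @inheritParams assign_operons
#' @return One row per operon: `operon_id, genome_id, contig_id, strand,
#'   start, end, n_genes` and a `members` list column of locus tags in gene
#'   order.
#' @export
call_operons <- function(tbl, max_gap = 150) {
  assign_operons(tbl, max_gap) %>%
    group_by(.data$operon_id, .data$genome_id, .data$contig_id, .data$strand) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      n_genes = n(),
      members = list(.data$locus_tag[order(.data$rank)]),
      .groups = "drop"
    ) %>%
    arrange(.data$genome_id, .data$contig_id, .data$start)
}
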