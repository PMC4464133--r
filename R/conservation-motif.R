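# Per-column identity profiles and two-tier consensus motifs numbered
# against a reference sequence.

.msa_matrix <- function(msa, ids = names(msa)) {
  missing <- setdiff(ids, names(msa))
  if (length(missing)) {
    abort(paste0("id(s) not in MSA: ", paste(missing, collapse = ", ")))
  }
  do.call(rbind, strsplit(unname(msa[ids]), ""))
}

#' Per-column identity profile of an alignment subgroup
#'
#' For each alignment column, the modal (consensus) residue over the non-gap
#' cells — ties broken alphabetically — and the fraction of subgroup
#' sequences carrying it. By default gaps count in the denominator, so a
#' mostly-gapped column can never look conserved; set `count_gaps = FALSE`
#' to divide by the non-gap count instead.
#'
#' @param msa Named character vector of aligned sequences ([read_msa()]).
#' @param ids Subgroup of sequence ids (default: all).
#' @param count_gaps Logical; include gaps in the identity denominator
#'   (default `TRUE`).
#' @return Tibble of class `remp_identity_profile` with `column,
#'   modal_residue, identity, n_gap, n_seq`.
#' @export
identity_profile <- function(msa, ids = names(msa), count_gaps = TRUE) {
  if (!length(ids)) abort("subgroup is empty")
  m <- .msa_matrix(msa, ids)
  n_seq <- nrow(m)
  out <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    is_gap <- col %in% c("-", ".")
    res <- col[!is_gap]
    if (length(res)) {
      tab <- table(res)
      top <- sort(names(tab)[tab == max(tab)])[1]
      count <- max(tab)
    } else {
      top <- NA_character_
      count <- 0L
    }
    denom <- if (count_gaps) n_seq else max(length(res), 1L)
    tibble(
      column = j,
      modal_residue = top,
      identity = count / denom,
      n_gap = sum(is_gap),
      n_seq = n_seq
    )
  })
  class(out) <- c("remp_identity_profile", class(out))
  out
}

#' Extract a tiered consensus motif
#'
#' Emits the alignment columns whose identity reaches `t1`, split into two
#' conservation tiers: `normal` for identity in `[t1, t2)` and `bold` for
#' identity `>= t2` (defaults 0.60 and 0.75). Positions are numbered against
#' a reference sequence: a column's number is the count of non-gap reference
#' residues up to and including it; columns where the reference is gapped
#' get the preceding residue number plus an insertion suffix (`84a`, `84b`,
#' ...).
#'
#' @param profile An [identity_profile()] of the subgroup.
#' @param msa The alignment the profile was computed from.
#' @param reference_id Id of the reference sequence used for numbering.
#' @param t1,t2 Identity thresholds of the normal and bold tiers.
#' @return Tibble of class `remp_motif` with `column, ref_position,
#'   insertion, ref_label, residue, identity, tier`; attribute
#'   `reference_id`.
#' @export
extract_motif <- function(profile, msa, reference_id, t1 = 0.60, t2 = 0.75) {
  stopifnot(t1 >= 0, t1 < t2, t2 <= 1)
  if (!reference_id %in% names(msa)) {
    abort(paste0("reference id not in MSA: ", reference_id))
  }
  ref <- strsplit(msa[[reference_id]], "")[[1]]
  if (length(ref) != nrow(profile)) {
    abort("profile and MSA disagree on alignment width")
  }
  ref_gap <- ref %in% c("-", ".")
  ref_pos <- cumsum(!ref_gap)
  ins <- character(length(ref))
  run <- 0L
  for (j in seq_along(ref)) {
    if (ref_gap[j]) {
      run <- run + 1L
      ins[j] <- letters[run]
    } else {
      run <- 0L
    }
  }
  out <- profile %>%
    mutate(
      ref_position = ref_pos[.data$column],
      insertion = ins[.data$column],
      ref_label = paste0(.data$ref_position, .data$insertion),
      residue = .data$modal_residue,
      tier = case_when(
        .data$identity >= t2 ~ "bold",
        .data$identity >= t1 ~ "normal",
        TRUE ~ NA_character_
      )
    ) %>%
    filter(!is.na(.data$tier), !is.na(.data$residue)) %>%
    select("column", "ref_position", "insertion", "ref_label", "residue",
      "identity", "tier")
  attr(out, "reference_id") <- reference_id
  attr(out, "thresholds") <- c(t1 = t1, t2 = t2)
  class(out) <- c("remp_motif", class(out))
  out
}

#' Render a motif as text
#'
#' One character per motif entry in column order; bold-tier residues are
#' marked with a trailing asterisk, and runs of skipped alignment columns
#' are shown as a single dash.
#'
#' @param motif A `remp_motif`.
#' @return A single string.
#' @export
render_motif <- function(motif) {
  if (!nrow(motif)) {
    return("")
  }
  piece <- paste0(motif$residue, ifelse(motif$tier == "bold", "*", ""))
  gapped <- c(FALSE, diff(motif$column) > 1)
  paste0(ifelse(gapped, "-", ""), piece, collapse = "")
}

#' Compare two motifs sharing a numbering scheme
#'
#' Reports positions present in only one motif and residue substitutions at
#' shared positions, in the compact `K37G` notation (residue of `a`,
#' reference position, residue of `b`).
#'
#' @param a,b Motifs from [extract_motif()] computed against the same
#'   reference sequence.
#' @return Tibble with `ref_label, type` (`only_a`, `only_b`,
#'   `substitution`), `residue_a, residue_b, notation`.
#' @export
compare_motifs <- function(a, b) {
  if (!identical(attr(a, "reference_id"), attr(b, "reference_id"))) {
    abort("motifs were numbered against different reference sequences")
  }
  full <- dplyr::full_join(
    select(as_tibble(a), "ref_label", "ref_position", "insertion", residue_a = "residue"),
    select(as_tibble(b), "ref_label", "ref_position", "insertion", residue_b = "residue"),
    by = c("ref_label", "ref_position", "insertion")
  )
  full %>%
    mutate(
      type = case_when(
        is.na(.data$residue_b) ~ "only_a",
        is.na(.data$residue_a) ~ "only_b",
        .data$residue_a != .data$residue_b ~ "substitution",
        TRUE ~ NA_character_
      ),
      notation = dplyr::if_else(
        .data$type == "substitution",
        paste0(.data$residue_a, .data$ref_label, .data$residue_b),
        NA_character_
      )
    ) %>%
    filter(!is.na(.data$type)) %>%
    arrange(.data$ref_position, .data$insertion) %>%
    select("ref_label", "type", "residue_a", "residue_b", "notation")
}
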