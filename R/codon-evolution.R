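# Codon alignments threaded from a protein MSA and pairwise Nei-Gojobori
# dN/dS with Jukes-Cantor correction.

#' Thread coding sequences onto a protein alignment
#'
#' Builds a codon alignment by walking each aligned protein sequence and
#' emitting its next CDS codon for every residue and a `---` gap triple for
#' every gap. A terminal stop codon on the CDS is trimmed; internal stops,
#' length mismatches and translation disagreements (code table 11) are
#' errors that name the offending sequence and position.
#'
#' @param protein_msa Named character vector of aligned protein sequences
#'   (equal lengths; gaps `-` or `.`), as from [read_msa()].
#' @param cds_map Named character vector of unaligned CDS nucleotide
#'   sequences covering every MSA id.
#' @return A `remp_codon_alignment`: list with `ids`, `codons` (id x column
#'   character matrix of codons / `---`), and `protein_msa`.
#' @export
thread_codons <- function(protein_msa, cds_map) {
  widths <- unique(nchar(protein_msa))
  if (length(widths) != 1) abort("protein MSA is ragged")
  missing <- setdiff(names(protein_msa), names(cds_map))
  if (length(missing)) {
    abort(paste0("CDS missing for id(s): ", paste(missing, collapse = ", ")))
  }
  code <- genetic_code()
  ids <- names(protein_msa)
  W <- widths
  codons <- matrix("---", nrow = length(ids), ncol = W, dimnames = list(ids, NULL))
  for (id in ids) {
    aln <- strsplit(protein_msa[[id]], "")[[1]]
    res_idx <- which(!aln %in% c("-", "."))
    cds <- toupper(cds_map[[id]])
    if (nchar(cds) %% 3 != 0) {
      abort(paste0("CDS length of ", id, " is not a multiple of 3"))
    }
    cd <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    # trim one terminal stop codon if present
    if (length(cd) && !is.na(code[cd[length(cd)]]) && code[cd[length(cd)]] == "*") {
      cd <- cd[-length(cd)]
    }
    if (length(cd) != length(res_idx)) {
      abort(paste0(
        "CDS of ", id, " has ", length(cd), " codons but the aligned protein has ",
        length(res_idx), " residues"
      ))
    }
    aa <- unname(code[cd])
    stops <- which(!is.na(aa) & aa == "*")
    if (length(stops)) {
      abort(paste0("internal stop codon in ", id, " at codon ", stops[1]))
    }
    known <- !is.na(aa)
    mism <- which(known & aa != aln[res_idx] & aln[res_idx] != "X")
    if (length(mism)) {
      abort(paste0(
        "translation mismatch for ", id, " at residue ", mism[1],
        ": codon ", cd[mism[1]], " -> ", aa[mism[1]],
        " but alignment has ", aln[res_idx][mism[1]]
      ))
    }
    codons[id, res_idx] <- cd
  }
  structure(
    list(ids = ids, codons = codons, protein_msa = protein_msa),
    class = "remp_codon_alignment"
  )
}

#' @export
print.remp_codon_alignment <- function(x, ...) {
  cat(
    "Codon alignment:", length(x$ids), "sequences x",
    ncol(x$codons), "codon columns\n"
  )
  invisible(x)
}

#' @rdname thread_codons
#' @param x A `remp_codon_alignment`.
#' @param ... Unused.
#' @export
glance.remp_codon_alignment <- function(x, ...) {
  tibble(
    n_seq = length(x$ids),
    n_columns = ncol(x$codons),
    prop_gap = mean(x$codons == "---")
  )
}

# comparable codon columns for a pair: both cells sense codons over ACGT
.comparable <- function(aln, id_a, id_b) {
  ca <- aln$codons[id_a, ]
  cb <- aln$codons[id_b, ]
  ok <- .is_sense(ca) & .is_sense(cb) &
    !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  list(a = ca[ok], b = cb[ok], cols = which(ok))
}

#' Pairwise Nei-Gojobori dN/dS between two aligned sequences
#'
#' Codon columns where either sequence has a gap, an ambiguous base or a
#' non-sense codon are skipped (pairwise deletion). Synonymous and
#' non-synonymous differences (`Sd`, `Nd`) are pathway-averaged per codon,
#' sites (`S`, `N`) are averaged over the two sequences, the proportions
#' `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected to `dS` and `dN`,
#' and the ratio `dN/dS` is returned. A comparison is flagged invalid when
#' `pS` or `pN` reaches the saturation cutoff 0.75, when no synonymous sites
#' were compared, or when `dS = 0` (identical-synonymous pairs give a 0/0
#' ratio; `dS = 0` with `dN > 0` is reported as `Inf` but still invalid for
#' percentile summaries).
#'
#' @param aln A `remp_codon_alignment` from [thread_codons()].
#' @param id_a,id_b Sequence identifiers in the alignment.
#' @return One-row tibble with columns `id_a, id_b, codons_compared, Sd, Nd,
#'   S, N, pS, pN, dS, dN, dnds, valid, fallback_pathways`.
#' @export
pairwise_dnds <- function(aln, id_a, id_b) {
  stopifnot(inherits(aln, "remp_codon_alignment"))
  if (!all(c(id_a, id_b) %in% aln$ids)) {
    abort("both ids must be present in the codon alignment")
  }
  .codon_tables()
  cmp <- .comparable(aln, id_a, id_b)
  L <- length(cmp$a)
  if (L == 0) abort(paste0("no comparable codons between ", id_a, " and ", id_b))
  ia <- unlist(.remp$codon_index[cmp$a], use.names = FALSE)
  ib <- unlist(.remp$codon_index[cmp$b], use.names = FALSE)
  lin <- cbind(ia, ib)
  Sd <- sum(.remp$diff_Sd[lin])
  Nd <- sum(.remp$diff_Nd[lin])
  fb <- sum(.remp$diff_fb[lin])
  S <- (sum(.remp$sites_S[ia]) + sum(.remp$sites_S[ib])) / 2
  N <- 3 * L - S
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- if (is.na(pS)) NA_real_ else jc_correct(min(pS, 1))
  dN <- if (is.na(pN)) NA_real_ else jc_correct(min(pN, 1))
  ratio <- if (is.na(dS) || is.na(dN)) {
    NA_real_
  } else if (dS == 0 && dN == 0) {
    NA_real_
  } else if (dS == 0) {
    Inf
  } else {
    dN / dS
  }
  valid <- !(is.na(pS) || pS >= 0.75 || is.na(pN) || pN >= 0.75 ||
    S == 0 || is.na(dS) || dS == 0)
  tibble(
    id_a = id_a, id_b = id_b, codons_compared = L,
    Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
    dS = dS, dN = dN, dnds = ratio, valid = valid,
    fallback_pathways = as.integer(fb)
  )
}

#' All intra-group pairwise dN/dS comparisons
#'
#' Runs [pairwise_dnds()] for every unordered pair of sequences that share a
#' group (by default the chaperone family; pairs across groups are never
#' compared, mirroring within-subgroup comparison designs).
#'
#' @param aln A `remp_codon_alignment`.
#' @param groups Tibble with columns `id`, `family` and optionally `phylum`.
#' @param within Character vector of grouping columns pairs must agree on
#'   (default `"family"`).
#' @return Tibble of pairwise results with the grouping columns of `id_a`
#'   attached, of class `remp_dnds_pairs`.
#' @export
dnds_pairs <- function(aln, groups, within = "family") {
  stopifnot(all(c("id", within) %in% names(groups)))
  groups <- groups %>% filter(.data$id %in% aln$ids)
  key <- do.call(paste, c(groups[within], sep = "\r"))
  out <- purrr::map_dfr(split(groups$id, key), function(ids) {
    if (length(ids) < 2) {
      return(NULL)
    }
    pairs <- utils::combn(ids, 2)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      pairwise_dnds(aln, pairs[1, k], pairs[2, k])
    })
  })
  if (nrow(out) == 0) {
    warn("no group holds two or more sequences; returning an empty pair table")
    out <- tibble(
      id_a = character(), id_b = character(), codons_compared = integer(),
      Sd = numeric(), Nd = numeric(), S = numeric(), N = numeric(),
      pS = numeric(), pN = numeric(), dS = numeric(), dN = numeric(),
      dnds = numeric(), valid = logical(), fallback_pathways = integer()
    )
  }
  out <- out %>%
    left_join(groups, by = c(id_a = "id")) %>%
    arrange(.data$id_a, .data$id_b)
  class(out) <- c("remp_dnds_pairs", class(out))
  out
}

#' @rdname dnds_pairs
#' @param x A `remp_dnds_pairs` tibble.
#' @param ... Unused.
#' @export
glance.remp_dnds_pairs <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_valid = sum(x$valid),
    n_invalid = sum(!x$valid),
    mean_dnds = mean(x$dnds[x$valid & is.finite(x$dnds)]),
    median_dnds = stats::median(x$dnds[x$valid & is.finite(x$dnds)])
  )
}

#' Percentile summaries of dN/dS per group
#'
#' Five-number summaries (min, 25th, median, 75th, max; linear interpolation
#' between order statistics) of the valid, finite dN/dS values per group —
#' the numbers a box-and-whisker panel of intra-phylum comparisons displays.
#' Invalid pairs (saturated pS/pN or dS = 0) are tallied separately, never
#' summarised.
#'
#' @param pairs Result of [dnds_pairs()] (or any tibble with `dnds`, `valid`
#'   and the grouping columns).
#' @param by Grouping columns (default `c("family", "phylum")` intersected
#'   with what is present).
#' @return Tibble of class `remp_group_summary` with `n_pairs` (valid),
#'   `n_invalid`, `min`, `p25`, `median`, `p75`, `max` and `mean` per group.
#'   Empty groups are dropped with a warning.
#' @export
group_summary <- function(pairs, by = intersect(c("family", "phylum"), names(pairs))) {
  if (!length(by)) abort("no grouping columns found")
  out <- pairs %>%
    group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::group_modify(function(d, key) {
      v <- d$dnds[d$valid & is.finite(d$dnds)]
      tibble(
        n_pairs = length(v),
        n_invalid = nrow(d) - length(v),
        min = .q(v, 0), p25 = .q(v, 0.25), median = .q(v, 0.5),
        p75 = .q(v, 0.75), max = .q(v, 1),
        mean = if (length(v)) mean(v) else NA_real_
      )
    }) %>%
    ungroup()
  empty <- out$n_pairs == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " group(s) had no valid pairs and were dropped"))
    out <- out[!empty, , drop = FALSE]
  }
  class(out) <- c("remp_group_summary", class(out))
  out
}

.q <- function(x, p) {
  if (!length(x)) {
    return(NA_real_)
  }
  unname(quantile(x, p, type = 7))
}

#' Per-column mean synonymous substitutions
#'
#' For every aligned codon column, the mean pathway-averaged synonymous
#' difference count (`Sd`) over all intra-group pairs whose cells are both
#' comparable in that column, together with the number of contributing
#' pairs. Column means weighted by their pair counts reconcile exactly with
#' the mean per-pair total Sd.
#'
#' @param aln A `remp_codon_alignment`.
#' @param ids Sequence ids forming the group (>= 2).
#' @param statistic `"mean"` (default) or `"sum"` over contributing pairs.
#' @return Tibble of class `remp_sd_profile`: `column, sd, n_pairs`.
#' @export
sd_profile <- function(aln, ids = aln$ids, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (length(ids) < 2) abort("need at least 2 sequences for an Sd profile")
  .codon_tables()
  W <- ncol(aln$codons)
  tot <- numeric(W)
  cnt <- integer(W)
  pairs <- utils::combn(ids, 2)
  for (k in seq_len(ncol(pairs))) {
    ca <- aln$codons[pairs[1, k], ]
    cb <- aln$codons[pairs[2, k], ]
    ok <- .is_sense(ca) & .is_sense(cb) & !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
    ia <- unlist(.remp$codon_index[ca[ok]], use.names = FALSE)
    ib <- unlist(.remp$codon_index[cb[ok]], use.names = FALSE)
    tot[ok] <- tot[ok] + .remp$diff_Sd[cbind(ia, ib)]
    cnt[ok] <- cnt[ok] + 1L
  }
  sd_col <- if (statistic == "mean") ifelse(cnt > 0, tot / cnt, 0) else tot
  out <- tibble(column = seq_len(W), sd = sd_col, n_pairs = cnt)
  class(out) <- c("remp_sd_profile", class(out))
  out
}
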