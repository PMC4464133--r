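# cis/trans/absent classification of chaperone loci, the frequency-of-gene-
# occurrence statistic, positional architecture summaries, and phi
# correlations on presence/absence matrices.

#' Define the cognate enzyme gene sets of a chaperone family
#'
#' A chaperone family (e.g. `torD`) can serve several complex iron-sulfur
#' molybdoenzyme (CISM) systems; each candidate system is a named set of gene
#' symbols (e.g. `torD_torAC = c("torA", "torC")`). Set order is meaningful:
#' ties in downstream matching are broken by it.
#'
#' @param family Chaperone gene symbol (lower case).
#' @param sets Named list of non-empty character vectors of gene symbols.
#' @return A `remp_cism` object.
#' @export
#' @examples
#' cism_definition("torD", list(
#'   torD_torAC = c("torA", "torC"),
#'   torD_fdh = c("fdhG", "fdhH", "fdhI")
#' ))
cism_definition <- function(family, sets) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("every cognate set must be named")
  }
  if (anyDuplicated(names(sets))) abort("cognate set labels must be unique")
  if (any(lengths(sets) == 0)) abort("cognate sets must be non-empty")
  structure(
    list(family = tolower(family), sets = lapply(sets, tolower)),
    class = "remp_cism"
  )
}

#' Default chaperone-family definitions
#'
#' The cognate operon gene sets of the five NarJ-subfamily chaperones (NarJ,
#' NarW, DmsD, TorD, YcdY) and the respiratory systems they are known to
#' serve: membrane-bound nitrate reductases (narGHI, narZYV), DMSO/selenate
#' reductases (dmsABC, ynfEFGH), TMAO reductase (torAC), formate
#' dehydrogenase (fdhGHI), the nrfD-hybA-bisC operon, tetrathionate
#' reductase (ttrABC), and the ycdX / hflC-mdaB partners of YcdY.
#'
#' @return Named list of [cism_definition()] objects keyed by family.
#' @export
default_cism_definitions <- function() {
  defs <- list(
    cism_definition("narJ", list(narJ_narGHI = c("narG", "narH", "narI"))),
    cism_definition("narW", list(narW_narZYV = c("narZ", "narY", "narV"))),
    cism_definition("dmsD", list(
      dmsD_dmsABC = c("dmsA", "dmsB", "dmsC"),
      dmsD_ynf = c("ynfE", "ynfF", "ynfG", "ynfH"),
      dmsD_fdh = c("fdhG", "fdhH", "fdhI"),
      dmsD_bisC_nrfD = c("nrfD", "hybA", "bisC")
    )),
    cism_definition("torD", list(
      torD_torAC = c("torA", "torC"),
      torD_fdh = c("fdhG", "fdhH", "fdhI"),
      torD_bisC_nrfD = c("nrfD", "hybA", "bisC"),
      torD_ttr = c("ttrA", "ttrB", "ttrC")
    )),
    cism_definition("ycdY", list(
      ycdY_ycdX = "ycdX",
      ycdY_hflC_mdaB = c("hflC", "mdaB")
    ))
  )
  setNames(defs, vapply(defs, function(d) d$family, character(1)))
}

#' Read chaperone-family definitions from YAML or JSON
#'
#' The file maps each family to named gene-symbol sets, e.g.
#' `torD: {torD_torAC: [torA, torC]}`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return Named list of [cism_definition()] objects.
#' @export
read_cism_definitions <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  defs <- purrr::imap(raw, function(sets, fam) {
    cism_definition(fam, lapply(sets, as.character))
  })
  setNames(defs, tolower(names(defs)))
}

# Which records match a gene symbol: exact (case-insensitive) gene_name match
# first, then case-insensitive substring match against the product text.
.matches_symbol <- function(tbl, symbol) {
  sym <- tolower(symbol)
  tbl$gene_name == sym |
    stringr::str_detect(tolower(tbl$product), stringr::fixed(sym))
}

TRANSPOSASE_RE <- stringr::regex("transposase|integrase|insertion sequence",
  ignore_case = TRUE
)

#' Classify one chaperone locus as cis, trans or absent
#'
#' A locus is *cis* when at least one gene of any cognate set shares its
#' operon call (incomplete operons still count as cis); otherwise *trans*
#' when at least one cognate set is completely present somewhere in the same
#' genome; otherwise *absent*. The matched set label is the set with the
#' largest overlap with the focal operon (cis) or the first complete set in
#' definition order (trans). `flanked_by_prev`/`_next` report the gene
#' symbols of the operon members immediately adjacent to the focal gene, and
#' `transposase` flags a transposase/integrase/insertion-sequence product
#' within the ORF-radius neighborhood.
#'
#' @param tbl Canonical annotation tibble.
#' @param locus_tag Focal chaperone locus.
#' @param definition A [cism_definition()].
#' @param operons Gene-level operon assignment from [assign_operons()];
#'   computed from `tbl` with `max_gap` if omitted.
#' @param max_gap Operon gap rule used when `operons` is missing.
#' @param radius ORF radius for the transposase flag and evidence collection.
#' @return One-row tibble: `genome_id, locus_tag, family, mode,
#'   matched_set_label, flanked_by_prev, flanked_by_next, transposase,
#'   evidence` (list column of matched gene symbol / locus tag pairs).
#' @export
classify_association <- function(tbl, locus_tag, definition,
                                 operons = NULL, max_gap = 150, radius = 10) {
  stopifnot(inherits(definition, "remp_cism"))
  if (!locus_tag %in% tbl$locus_tag) {
    abort(paste0("locus_tag not found: ", locus_tag))
  }
  if (is.null(operons)) operons <- assign_operons(tbl, max_gap)
  focal <- operons[operons$locus_tag == locus_tag, ]
  genome <- operons[operons$genome_id == focal$genome_id, ]
  op_members <- genome %>%
    filter(.data$operon_id == focal$operon_id) %>%
    arrange(.data$rank)

  # overlap of each cognate set with the focal operon (focal gene excluded)
  others <- op_members[op_members$locus_tag != locus_tag, , drop = FALSE]
  overlap <- vapply(definition$sets, function(set) {
    sum(vapply(set, function(sym) any(.matches_symbol(others, sym)), logical(1)))
  }, numeric(1))

  mode <- "absent"
  label <- NA_character_
  evidence <- list()
  if (any(overlap > 0)) {
    mode <- "cis"
    label <- names(definition$sets)[which.max(overlap)]
    set <- definition$sets[[label]]
    hits <- purrr::map_dfr(set, function(sym) {
      m <- others[.matches_symbol(others, sym), , drop = FALSE]
      if (nrow(m)) tibble(gene_symbol = sym, locus_tag = m$locus_tag) else NULL
    })
    evidence <- list(hits)
  } else {
    complete <- vapply(definition$sets, function(set) {
      all(vapply(set, function(sym) any(.matches_symbol(genome, sym)), logical(1)))
    }, logical(1))
    if (any(complete)) {
      mode <- "trans"
      label <- names(definition$sets)[which(complete)[1]]
      set <- definition$sets[[label]]
      hits <- purrr::map_dfr(set, function(sym) {
        m <- genome[.matches_symbol(genome, sym), , drop = FALSE]
        tibble(gene_symbol = sym, locus_tag = m$locus_tag)
      })
      evidence <- list(hits)
    } else {
      evidence <- list(tibble(gene_symbol = character(), locus_tag = character()))
    }
  }

  pos <- match(locus_tag, op_members$locus_tag)
  prev_sym <- if (pos > 1) op_members$gene_name[pos - 1] else NA_character_
  next_sym <- if (pos < nrow(op_members)) op_members$gene_name[pos + 1] else NA_character_

  nb <- extract_neighborhood(tbl, locus_tag, radius)
  transposase <- any(stringr::str_detect(nb$product, TRANSPOSASE_RE))

  tibble(
    genome_id = focal$genome_id,
    locus_tag = locus_tag,
    family = definition$family,
    mode = mode,
    matched_set_label = label,
    flanked_by_prev = prev_sym,
    flanked_by_next = next_sym,
    transposase = transposase,
    evidence = evidence
  )
}

#' Classify every chaperone locus in a multi-genome table
#'
#' Focal loci are the records whose `gene_name` equals one of the definition
#' families.
#'
#' @param tbl Canonical annotation tibble (one or many genomes).
#' @param definitions Named list of [cism_definition()]s, as from
#'   [default_cism_definitions()].
#' @inheritParams classify_association
#' @return Row-bound [classify_association()] results.
#' @export
classify_associations <- function(tbl, definitions = default_cism_definitions(),
                                  max_gap = 150, radius = 10) {
  operons <- assign_operons(tbl, max_gap)
  fams <- tolower(names(definitions))
  focal <- tbl %>% filter(.data$gene_name %in% fams)
  purrr::map_dfr(seq_len(nrow(focal)), function(i) {
    fam <- focal$gene_name[i]
    classify_association(
      tbl, focal$locus_tag[i], definitions[[fam]],
      operons = operons, radius = radius
    )
  })
}

#' Frequency of gene occurrence around chaperone loci
#'
#' For each queried gene symbol, counts the focal loci whose ORF-radius
#' neighborhood contains the gene (`n_gene`; a gene present twice in one
#' neighborhood counts once), the total loci examined (`n_locus`), and the
#' frequency-of-gene-occurrence statistic
#' `F_G = (n_gene / n_locus) / O`, where `O` is the number of chaperone
#' operons examined. The raw fraction `n_gene / n_locus` is reported
#' alongside `F_G` because co-occurrence percentages quoted for operon
#' architectures correspond to the raw fraction.
#'
#' @param neighborhoods Neighborhood tibble from [extract_neighborhoods()]
#'   for the loci of one chaperone family (focal rows are ignored).
#' @param n_operons Number of chaperone operons examined (`O`); must be > 0.
#' @param symbols Character vector of gene symbols to tabulate.
#' @return Tibble with columns `gene_symbol, n_gene, n_locus, raw_fraction,
#'   f_g`.
#' @export
gene_frequency <- function(neighborhoods, n_operons, symbols) {
  if (n_operons <= 0) {
    abort("F_G is undefined for n_operons = 0")
  }
  nb <- neighborhoods %>% filter(.data$side != "focal")
  loci <- unique(neighborhoods$focal_locus_tag)
  n_locus <- length(loci)
  if (n_locus == 0) abort("no focal loci in neighborhoods")
  purrr::map_dfr(symbols, function(sym) {
    hit <- nb[.matches_symbol(nb, sym), , drop = FALSE]
    n_gene <- dplyr::n_distinct(hit$focal_locus_tag)
    tibble(
      gene_symbol = sym,
      n_gene = n_gene,
      n_locus = n_locus,
      raw_fraction = n_gene / n_locus,
      f_g = (n_gene / n_locus) / n_operons
    )
  })
}

#' Fraction of cis loci flanked by a given gene pair
#'
#' Among the cis-classified loci of one family, the fraction whose immediate
#' operon neighbors match the unordered pair of gene symbols (e.g. narJ
#' sitting between narH and narI).
#'
#' @param results Association tibble from [classify_associations()].
#' @param family Chaperone family.
#' @param flank_pair Character vector of two gene symbols (unordered).
#' @return A single number in `[0, 1]`.
#' @export
positional_profile <- function(results, family, flank_pair) {
  stopifnot(length(flank_pair) == 2)
  cis <- results %>%
    filter(.data$family == !!tolower(family), .data$mode == "cis")
  if (nrow(cis) == 0) {
    abort(paste0("no cis loci for family ", family))
  }
  pair <- sort(tolower(flank_pair))
  hit <- vapply(seq_len(nrow(cis)), function(i) {
    fl <- sort(c(
      dplyr::coalesce(cis$flanked_by_prev[i], ""),
      dplyr::coalesce(cis$flanked_by_next[i], "")
    ))
    identical(fl, pair)
  }, logical(1))
  mean(hit)
}

#' Build a genome-by-system presence/absence matrix
#'
#' A cell is 1 when every gene of the labelled cognate set is found in the
#' genome (by gene symbol or product match).
#'
#' @param tbl Canonical annotation tibble covering several genomes.
#' @param definitions Named list of [cism_definition()]s; every labelled set
#'   becomes a column.
#' @return Tibble with a `genome_id` column and one 0/1 column per set label.
#' @export
presence_matrix <- function(tbl, definitions = default_cism_definitions()) {
  sets <- purrr::flatten(purrr::map(definitions, "sets"))
  genomes <- unique(tbl$genome_id)
  out <- purrr::map_dfr(genomes, function(g) {
    sub <- tbl[tbl$genome_id == g, , drop = FALSE]
    vals <- vapply(sets, function(set) {
      as.integer(all(vapply(set, function(sym) any(.matches_symbol(sub, sym)), logical(1))))
    }, integer(1))
    dplyr::bind_cols(tibble(genome_id = g), as_tibble(as.list(vals)))
  })
  out
}

#' Phi correlations between binary presence/absence columns
#'
#' Pearson correlation of 0/1 columns, i.e. the phi coefficient of each 2x2
#' contingency table. Cells involving a constant column are undefined and
#' returned as `NA` (never coerced to 0); the diagonal is 1 for columns with
#' positive variance.
#'
#' @param m Presence/absence tibble from [presence_matrix()] (a `genome_id`
#'   column is ignored) or a binary matrix. Needs at least 2 rows and 2
#'   columns.
#' @return A symmetric correlation matrix of class `remp_phi`.
#' @export
presence_correlation <- function(m) {
  if (is.data.frame(m)) {
    m <- as.matrix(m[setdiff(names(m), "genome_id")])
  }
  if (nrow(m) < 2) abort("need at least 2 genomes for presence correlations")
  if (ncol(m) < 2) abort("need at least 2 presence columns")
  if (!all(m %in% c(0, 1))) abort("presence matrix must be binary")
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  vars <- apply(m, 2, stats::var)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (vars[i] > 0 && vars[j] > 0) {
        # phi from the 2x2 contingency counts
        a <- sum(m[, i] == 1 & m[, j] == 1)
        b <- sum(m[, i] == 1 & m[, j] == 0)
        c_ <- sum(m[, i] == 0 & m[, j] == 1)
        d <- sum(m[, i] == 0 & m[, j] == 0)
        r[i, j] <- (a * d - b * c_) /
          sqrt((a + b) * (c_ + d) * (a + c_) * (b + d))
      }
    }
  }
  structure(r, class = c("remp_phi", "matrix"))
}

#' @export
print.remp_phi <- function(x, ...) {
  cat("Phi (presence/absence) correlation matrix:\n")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' @rdname presence_correlation
#' @param x A `remp_phi` matrix.
#' @param ... Unused.
#' @export
tidy.remp_phi <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "phi", stringsAsFactors = FALSE)) %>%
    rename(column_a = "Var1", column_b = "Var2") %>%
    filter(match(.data$column_a, colnames(m)) < match(.data$column_b, colnames(m)))
}
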