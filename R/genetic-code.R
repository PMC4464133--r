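# Codon-level machinery shared by the dN/dS and simulation code.
#
# Everything is computed under NCBI translation table 11 (bacteria/archaea).
# Site fractions and pathway-averaged difference counts follow the
# Nei-Gojobori (1986) convention with equal pathway weighting; single-step
# changes to stop codons are excluded from both site denominators and
# pathways, so S + N = 3 exactly for every sense codon.

.remp <- new.env(parent = emptyenv())

#' The genetic code used throughout the package
#'
#' Returns NCBI translation table 11 (bacterial/archaeal/plant-plastid) as a
#' named character vector mapping the 64 codons to one-letter amino acids,
#' with `*` for stops. All translation, site counting and simulation in the
#' package uses this table; it is fixed because the chaperones analysed are
#' prokaryotic.
#'
#' @return Named character vector of length 64.
#' @export
#' @examples
#' genetic_code()[["ATG"]]
genetic_code <- function() {
  if (is.null(.remp$code)) {
    .remp$code <- Biostrings::getGeneticCode("11")
  }
  .remp$code
}

.sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

.translate_codon <- function(codon) {
  aa <- genetic_code()[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

.is_sense <- function(codon) {
  code <- genetic_code()
  !is.na(code[codon]) & code[codon] != "*"
}

#' Synonymous and non-synonymous site counts of a codon
#'
#' For each of the three codon positions, considers the three single-nucleotide
#' mutants; mutants that create a stop codon are dropped, and the position
#' contributes the fraction of the remaining mutants that are synonymous.
#' `S` is the sum of the three fractions and `N = 3 - S`, so `S + N = 3`
#' exactly for every sense codon.
#'
#' @param codon A single sense codon (3 characters, ACGT).
#' @return A named numeric vector `c(S = , N = )`, or `NA`s (with no error)
#'   for a stop or ambiguous codon, which callers treat as a skip signal.
#' @export
#' @examples
#' codon_sites("TTT") # S = 1/3: only TTT->TTC is synonymous
#' codon_sites("TGG") # S = 0: tryptophan has no synonymous neighbour
codon_sites <- function(codon) {
  .codon_tables()
  i <- .remp$codon_index[[codon]]
  if (is.null(i)) {
    return(c(S = NA_real_, N = NA_real_))
  }
  s <- unname(.remp$sites_S[i])
  c(S = s, N = 3 - s)
}

#' Pathway-averaged synonymous/non-synonymous differences between two codons
#'
#' Counts the synonymous (`Sd`) and non-synonymous (`Nd`) single-nucleotide
#' steps separating two sense codons, averaged with equal weight over all
#' orderings of the differing positions. Orderings that pass through a stop
#' codon are excluded and the remaining orderings re-weighted equally;
#' `Sd + Nd` equals the number of differing positions. In the degenerate case
#' where every ordering is blocked by stops, each differing position is
#' classified independently against both codon contexts and the result is
#' flagged.
#'
#' @param codon_a,codon_b Sense codons (3 characters, ACGT).
#' @return Named numeric vector `c(Sd = , Nd = , fallback = 0/1)`.
#' @export
#' @examples
#' codon_differences("TTT", "TTC") # one synonymous step
#' codon_differences("TTT", "GTA") # averaged over the 2 orderings
codon_differences <- function(codon_a, codon_b) {
  .codon_tables()
  i <- .remp$codon_index[[codon_a]]
  j <- .remp$codon_index[[codon_b]]
  if (is.null(i) || is.null(j)) {
    abort("codon_differences() requires sense codons under code table 11")
  }
  c(
    Sd = .remp$diff_Sd[i, j],
    Nd = .remp$diff_Nd[i, j],
    fallback = .remp$diff_fb[i, j]
  )
}

# Build the lookup tables once: per-codon site fractions and the 61 x 61
# pathway-averaged difference matrices.
.codon_tables <- function() {
  if (!is.null(.remp$sites_S)) {
    return(invisible(NULL))
  }
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  idx <- setNames(as.list(seq_along(sense)), sense)

  sites_S <- numeric(length(sense))
  for (k in seq_along(sense)) {
    chars <- strsplit(sense[k], "")[[1]]
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(bases, chars[p])
      muts <- vapply(alts, function(b) {
        m <- chars
        m[p] <- b
        paste(m, collapse = "")
      }, character(1))
      aa <- code[muts]
      keep <- aa != "*"
      if (any(keep)) {
        s <- s + sum(aa[keep] == code[sense[k]]) / sum(keep)
      }
    }
    sites_S[k] <- s
  }

  n <- length(sense)
  Sd <- matrix(0, n, n)
  Nd <- matrix(0, n, n)
  Fb <- matrix(0, n, n)
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  split_codons <- strsplit(sense, "")
  for (i in seq_len(n)) {
    a <- split_codons[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      b <- split_codons[[j]]
      pos <- which(a != b)
      k <- length(pos)
      if (k == 1) {
        syn <- code[sense[i]] == code[sense[j]]
        Sd[i, j] <- as.numeric(syn)
        Nd[i, j] <- as.numeric(!syn)
        next
      }
      perms <- if (k == 2) perms2 else perms3
      tot_s <- 0
      tot_n <- 0
      n_ok <- 0
      for (pm in perms) {
        cur <- a
        s <- 0
        nn <- 0
        ok <- TRUE
        for (step in pm) {
          nxt <- cur
          nxt[pos[step]] <- b[pos[step]]
          nxt_codon <- paste(nxt, collapse = "")
          if (code[nxt_codon] == "*") {
            ok <- FALSE
            break
          }
          if (code[paste(cur, collapse = "")] == code[nxt_codon]) s <- s + 1 else nn <- nn + 1
          cur <- nxt
        }
        if (ok) {
          tot_s <- tot_s + s
          tot_n <- tot_n + nn
          n_ok <- n_ok + 1
        }
      }
      if (n_ok > 0) {
        Sd[i, j] <- tot_s / n_ok
        Nd[i, j] <- tot_n / n_ok
      } else {
        # every ordering blocked: classify each differing position in both
        # codon contexts independently (skipping contexts that hit a stop)
        s <- 0
        nn <- 0
        for (p in pos) {
          cls <- c()
          for (ctx in list(a, b)) {
            other <- if (identical(ctx, a)) b else a
            m <- ctx
            m[p] <- other[p]
            mc <- paste(m, collapse = "")
            if (code[mc] != "*") {
              cls <- c(cls, code[paste(ctx, collapse = "")] == code[mc])
            }
          }
          if (length(cls)) {
            s <- s + mean(cls)
            nn <- nn + mean(!cls)
          } else {
            nn <- nn + 1
          }
        }
        Sd[i, j] <- s
        Nd[i, j] <- nn
        Fb[i, j] <- 1
      }
    }
  }
  .remp$codon_index <- idx
  .remp$sense <- sense
  .remp$sites_S <- setNames(sites_S, sense)
  .remp$diff_Sd <- Sd
  .remp$diff_Nd <- Nd
  .remp$diff_fb <- Fb
  invisible(NULL)
}

#' Jukes-Cantor distance correction
#'
#' Corrects an observed proportion of differences `p` for multiple hits:
#' `d = -(3/4) ln(1 - (4/3) p)`. The correction is undefined at and above the
#' saturation cutoff of 0.75 (the log argument reaches zero); such values are
#' returned as `NA`, not raised as errors, so downstream code can mark the
#' pair invalid rather than crash.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Numeric vector of corrected distances; `NA` where `p >= 0.75`.
#' @export
#' @examples
#' jc_correct(0)
#' jc_correct(0.5) # ~0.824
#' jc_correct(0.75) # NA: saturated
jc_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - (4 / 3) * p[ok])
  out
}
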