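test_that("codon threading follows the protein alignment", {
  aln <- thread_codons(c(s1 = "M-A"), c(s1 = "ATGGCT"))
  expect_equal(unname(aln$codons["s1", ]), c("ATG", "---", "GCT"))
  # terminal stop trimmed
  aln2 <- thread_codons(c(s1 = "MA"), c(s1 = "ATGGCTTAA"))
  expect_equal(unname(aln2$codons["s1", ]), c("ATG", "GCT"))
})

test_that("threading errors name the sequence and position", {
  expect_error(thread_codons(c(s1 = "MKA"), c(s1 = "ATGTAAGCT")), "internal stop")
  expect_error(
    thread_codons(c(s1 = "MA"), c(s1 = "ATGGCTGCT")),
    "3 codons.*2 residues"
  )
  expect_error(thread_codons(c(s1 = "MW"), c(s1 = "ATGGCT")), "mismatch")
  expect_error(thread_codons(c(s1 = "MA"), c(s2 = "ATGGCT")), "s1")
})

test_that("site counts match enumeration for the worked examples", {
  expect_equal(codon_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(codon_sites("TGG"), c(S = 0, N = 3))
  expect_true(is.na(codon_sites("TAA")["S"])) # stop: skip signal, no crash
  # S + N = 3 for every sense codon, by construction
  for (cd in oracle_sense_codons()) {
    s <- codon_sites(cd)
    expect_equal(unname(s["S"] + s["N"]), 3)
  }
})

test_that("difference counts match the pathway oracle on worked examples", {
  expect_equal(codon_differences("TTT", "TTT")[c("Sd", "Nd")], c(Sd = 0, Nd = 0))
  expect_equal(codon_differences("TTT", "TTC")[c("Sd", "Nd")], c(Sd = 1, Nd = 0))
  # two differing positions, averaged over both orderings
  expect_equal(
    codon_differences("TTT", "GTA")[c("Sd", "Nd")],
    c(Sd = 0.5, Nd = 1.5)
  )
  expect_equal(
    codon_differences("TTT", "GTA")[c("Sd", "Nd")],
    oracle_diffs("TTT", "GTA")
  )
  expect_error(codon_differences("TAA", "TTT"), "sense")
})

test_that("Jukes-Cantor correction matches its closed form and cutoff", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.5), -0.75 * log(1 / 3))
  expect_true(is.na(jc_correct(0.75)))
  expect_true(is.na(jc_correct(0.9)))
  grid <- seq(0, 0.74, by = 0.01)
  d <- jc_correct(grid)
  expect_true(all(diff(d) > 0)) # strictly increasing
  expect_true(all(d >= grid)) # correction never shrinks p
})

test_that("identical sequences give an undefined, invalid ratio", {
  cd <- random_codons(50)
  aln <- aln_from_codons(a = cd, b = cd)
  p <- pairwise_dnds(aln, "a", "b")
  expect_equal(p$Sd, 0)
  expect_equal(p$Nd, 0)
  expect_equal(p$pS, 0)
  expect_true(is.na(p$dnds))
  expect_false(p$valid)
})

test_that("a single synonymous change gives dN = 0 and a valid zero ratio", {
  set.seed(9)
  cd <- random_codons(100)
  cd2 <- cd
  cd2[50] <- "TTC" # replace with a codon one synonymous step away
  cd[50] <- "TTT"
  aln <- aln_from_codons(a = cd, b = cd2)
  p <- pairwise_dnds(aln, "a", "b")
  expect_equal(p$Sd, 1)
  expect_equal(p$Nd, 0)
  expect_equal(p$dN, 0)
  expect_equal(p$dnds, 0)
  expect_true(p$valid)
})

test_that("gap and ambiguity columns are skipped pairwise", {
  aln <- thread_codons(
    c(a = "MKA-", b = "MK-C"),
    c(a = "ATGAAAGCT", b = "ATGAANTGT")
  )
  p <- pairwise_dnds(aln, "a", "b")
  # column 2 has an ambiguous base in b; columns 3-4 are half-gapped
  expect_equal(p$codons_compared, 1)
  expect_equal(p$S + p$N, 3 * p$codons_compared)
})

test_that("pairwise dN/dS is symmetric and additive in Sd + Nd", {
  ds <- generate_dataset(n_genomes = 4, seed = 21)
  aln <- thread_codons(ds$msa, ds$cds)
  g <- ds$groups[ds$groups$family == "narj", ]
  a <- g$id[1]
  b <- g$id[2]
  p_ab <- pairwise_dnds(aln, a, b)
  p_ba <- pairwise_dnds(aln, b, a)
  expect_equal(p_ab[c("Sd", "Nd", "S", "N", "pS", "pN", "dS", "dN", "dnds")],
    p_ba[c("Sd", "Nd", "S", "N", "pS", "pN", "dS", "dN", "dnds")],
    tolerance = 1e-12
  )
  # Sd + Nd equals the plain nucleotide difference count over compared codons
  ca <- aln$codons[a, ]
  cb <- aln$codons[b, ]
  diffs <- sum(mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, ca, cb))
  expect_equal(p_ab$Sd + p_ab$Nd, diffs, tolerance = 1e-9)
  expect_equal(p_ab$S + p_ab$N, 3 * p_ab$codons_compared, tolerance = 1e-9)
})

test_that("saturated pairs are flagged invalid by the 0.75 cutoff", {
  # glycine codons differing at the fully degenerate third position:
  # every difference is synonymous and every synonymous site is hit,
  # so pS = 1 and the correction cannot be applied
  a <- rep("GGA", 50)
  b <- rep("GGC", 50)
  aln <- aln_from_codons(a = a, b = b)
  p <- pairwise_dnds(aln, "a", "b")
  expect_gte(p$pS, 0.75)
  expect_true(is.na(p$dS))
  expect_false(p$valid)
})

test_that("group summaries report linear-interpolation percentiles", {
  pairs <- tibble::tibble(
    family = "narj", phylum = "X",
    dnds = c(0.2, 0.4, 0.6, 0.8, 1.0),
    valid = TRUE
  )
  s <- group_summary(pairs)
  expect_equal(s$min, 0.2)
  expect_equal(s$p25, 0.4)
  expect_equal(s$median, 0.6)
  expect_equal(s$p75, 0.8)
  expect_equal(s$max, 1.0)
  expect_equal(s$n_pairs, 5)
  one <- group_summary(tibble::tibble(
    family = "narj", phylum = "X", dnds = 0.3, valid = TRUE
  ))
  expect_equal(unlist(one[c("min", "p25", "median", "p75", "max")]),
    rep(0.3, 5),
    ignore_attr = TRUE
  )
})

test_that("invalid pairs are tallied but never summarised", {
  pairs <- tibble::tibble(
    family = "narj", phylum = "X",
    dnds = c(0.5, 0.7, NA, Inf),
    valid = c(TRUE, TRUE, FALSE, FALSE)
  )
  s <- group_summary(pairs)
  expect_equal(s$n_pairs, 2)
  expect_equal(s$n_invalid, 2)
  expect_equal(s$max, 0.7)
  expect_warning(
    group_summary(tibble::tibble(
      family = "x", phylum = "Y", dnds = NA_real_, valid = FALSE
    )),
    "no valid pairs"
  )
})

test_that("an invariant column has zero Sd and profiles reconcile with totals", {
  ds <- generate_dataset(n_genomes = 6, seed = 5, conserved_columns = 10)
  aln <- thread_codons(ds$msa, ds$cds)
  ids <- ds$groups$id[ds$groups$family == "narj"]
  prof <- sd_profile(aln, ids)
  expect_equal(prof$sd[10], 0)
  # weighted column means reconcile with the mean per-pair total Sd
  pairs <- utils::combn(ids, 2)
  totals <- vapply(seq_len(ncol(pairs)), function(k) {
    pairwise_dnds(aln, pairs[1, k], pairs[2, k])$Sd
  }, numeric(1))
  expect_equal(sum(prof$sd * prof$n_pairs) / ncol(pairs), mean(totals),
    tolerance = 1e-9
  )
})

test_that("glance() summarises alignments and pair sets", {
  ds <- generate_dataset(n_genomes = 4, seed = 2)
  aln <- thread_codons(ds$msa, ds$cds)
  g <- glance(aln)
  expect_equal(g$n_seq, length(ds$msa))
  pairs <- dnds_pairs(aln, ds$groups, within = "family")
  gp <- glance(pairs)
  expect_equal(gp$n_pairs, nrow(pairs))
  expect_true(gp$mean_dnds > 0)
})
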