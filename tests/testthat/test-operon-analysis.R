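narj_def <- cism_definition("narJ", list(narJ_narGHI = c("narG", "narH", "narI")))
tord_def <- cism_definition("torD", list(
  torD_torAC = c("torA", "torC"),
  torD_fdh = c("fdhG", "fdhH", "fdhI")
))

test_that("a chaperone inside its operon is classified cis with its flanks", {
  tbl <- contig_tbl(c("narG", "narH", "narJ", "narI"))
  res <- classify_association(tbl, tbl$locus_tag[3], narj_def)
  expect_equal(res$mode, "cis")
  expect_equal(res$matched_set_label, "narJ_narGHI")
  expect_equal(res$flanked_by_prev, "narh")
  expect_equal(res$flanked_by_next, "nari")
  expect_setequal(res$evidence[[1]]$gene_symbol, c("narg", "narh", "nari"))
})

test_that("a lone chaperone with a complete cognate operon elsewhere is trans", {
  tbl <- dplyr::bind_rows(
    contig_tbl("torD", contig = "c1", locus_prefix = "A"),
    contig_tbl(c("torA", "torC"), contig = "c2", locus_prefix = "B")
  )
  res <- classify_association(tbl, "AG1_001", tord_def)
  expect_equal(res$mode, "trans")
  expect_equal(res$matched_set_label, "torD_torAC")
})

test_that("a chaperone with no cognate genes anywhere is absent", {
  tbl <- dplyr::bind_rows(
    contig_tbl("torD", contig = "c1", locus_prefix = "A"),
    contig_tbl(c("fdhG", "fdhH"), contig = "c2", locus_prefix = "B") # incomplete set
  )
  res <- classify_association(tbl, "AG1_001", tord_def)
  expect_equal(res$mode, "absent")
  expect_true(is.na(res$matched_set_label))
})

test_that("incomplete operons still count as cis and pick the largest set", {
  # torD co-operonic with fdhG+fdhH only: cis via the 2-gene overlap
  tbl <- contig_tbl(c("fdhG", "fdhH", "torD"))
  res <- classify_association(tbl, tbl$locus_tag[3], tord_def)
  expect_equal(res$mode, "cis")
  expect_equal(res$matched_set_label, "torD_fdh")
})

test_that("transposase products within the radius are flagged", {
  tbl <- contig_tbl(c("narG", "narH", "narJ", "narI", ""),
    products = c(
      "narG protein", "narH protein", "narJ protein", "narI protein",
      "IS5 family transposase"
    )
  )
  res <- classify_association(tbl, tbl$locus_tag[3], narj_def)
  expect_true(res$transposase)
  far <- contig_tbl(c("narG", "narH", "narJ", "narI"))
  expect_false(classify_association(far, far$locus_tag[3], narj_def)$transposase)
})

test_that("gene frequency follows F_G = (n_gene/n_locus)/O by direct substitution", {
  # 3 narJ loci on separate contigs; narK within the radius of 2 of them
  tbl <- dplyr::bind_rows(
    contig_tbl(c("narK", "narJ"), contig = "c1", locus_prefix = "A"),
    contig_tbl(c("narK", "narJ"), contig = "c2", locus_prefix = "B"),
    contig_tbl(c("", "narJ"), contig = "c3", locus_prefix = "C")
  )
  loci <- tbl$locus_tag[tbl$gene_name == "narj"]
  nb <- extract_neighborhoods(tbl, loci, radius = 10)
  fg <- gene_frequency(nb, n_operons = 3, symbols = c("narK", "ycdX"))
  narK <- fg[fg$gene_symbol == "narK", ]
  expect_equal(narK$n_gene, 2)
  expect_equal(narK$n_locus, 3)
  expect_equal(narK$raw_fraction, 2 / 3)
  expect_equal(narK$f_g, 2 / 9)
  # a symbol never observed
  expect_equal(fg$f_g[fg$gene_symbol == "ycdX"], 0)
  expect_error(gene_frequency(nb, 0, "narK"), "undefined")
})

test_that("gene frequency counts loci, not occurrences, and ignores order", {
  tbl <- contig_tbl(c("narK", "narJ", "narK"), contig = "c1")
  nb <- extract_neighborhoods(tbl, tbl$locus_tag[2], radius = 10)
  fg <- gene_frequency(nb, 1, "narK")
  expect_equal(fg$n_gene, 1)
  expect_equal(fg$raw_fraction, 1)
  expect_equal(fg$f_g, 1)
  shuffled <- nb[rev(seq_len(nrow(nb))), ]
  expect_equal(gene_frequency(shuffled, 1, "narK"), fg)
})

test_that("positional profile measures the flanking-pair fraction of cis loci", {
  res <- tibble::tibble(
    family = "narj",
    mode = c(rep("cis", 10), "trans"),
    flanked_by_prev = c(rep("narh", 9), "narg", "narh"),
    flanked_by_next = c(rep("nari", 9), "nari", "nari")
  )
  expect_equal(positional_profile(res, "narJ", c("narI", "narH")), 0.9)
  expect_error(
    positional_profile(res[res$mode == "trans", ], "narj", c("narH", "narI")),
    "no cis"
  )
})

test_that("phi correlation handles identical, complementary and mixed columns", {
  m <- tibble::tibble(
    genome_id = paste0("g", 1:8),
    a = c(1, 1, 1, 1, 0, 0, 0, 0),
    b = c(1, 1, 1, 1, 0, 0, 0, 0),
    c = c(0, 0, 0, 0, 1, 1, 1, 1),
    d = c(1, 1, 1, 0, 1, 0, 0, 0) # 2x2 table (3,1;1,3) against a
  )
  r <- presence_correlation(m)
  expect_equal(unclass(r)["a", "b"], 1.0)
  expect_equal(unclass(r)["a", "c"], -1.0)
  expect_equal(unclass(r)["a", "d"], 0.5)
  expect_true(isSymmetric(unclass(r)))
})

test_that("constant presence columns give NA, never zero", {
  m <- tibble::tibble(genome_id = paste0("g", 1:4), a = c(1, 0, 1, 0), k = c(1, 1, 1, 1))
  r <- presence_correlation(m)
  expect_true(is.na(unclass(r)["a", "k"]))
  expect_true(is.na(unclass(r)["k", "k"]))
  expect_equal(unclass(r)["a", "a"], 1)
  expect_error(presence_correlation(m[1, ]), "2 genomes")
})

test_that("phi equals the Pearson correlation of the binary columns", {
  set.seed(404)
  for (rep in 1:5) {
    m <- matrix(rbinom(40, 1, 0.5), nrow = 10)
    colnames(m) <- paste0("c", 1:4)
    keep <- apply(m, 2, function(x) length(unique(x)) > 1)
    m <- m[, keep, drop = FALSE]
    if (ncol(m) < 2) next
    r <- unclass(presence_correlation(m))
    expect_equal(r, stats::cor(m), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("tidy() on a phi matrix returns the upper-triangle pairs", {
  m <- tibble::tibble(genome_id = c("a", "b", "c"), x = c(1, 0, 1), y = c(0, 1, 1))
  td <- tidy(presence_correlation(m))
  expect_equal(nrow(td), 1)
  expect_named(td, c("column_a", "column_b", "phi"))
})
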