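test_that("generation is deterministic under a fixed seed", {
  a <- generate_dataset(n_genomes = 4, seed = 99)
  b <- generate_dataset(n_genomes = 4, seed = 99)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$msa, b$msa)
  expect_identical(a$cds, b$cds)
  c_ <- generate_dataset(n_genomes = 4, seed = 100)
  expect_false(identical(a$cds, c_$cds))
})

test_that("generated annotations always satisfy the table invariants", {
  set.seed(17)
  for (rep in 1:6) {
    tmpl <- genome_template(
      phylum = "P",
      layouts = list(operon_layout(
        core = c("narG", "narH", "narI"), chaperone = "narJ",
        cis_index = sample(1:4, 1),
        cis_prob = runif(1, 0.3, 1) * 0.7, trans_prob = 0.2,
        flank_prob = runif(1)
      )),
      n_filler = sample(2:8, 1)
    )
    tbl <- generate_genome(tmpl, paste0("R", rep), seed = 1000 + rep)
    # as_annotation re-validates every invariant; a no-op means they hold
    expect_equal(
      as.data.frame(as_annotation(tbl)),
      as.data.frame(tbl)[, ANNOTATION_COLS_FOR_TEST()],
      ignore_attr = TRUE
    )
    ranks <- split(tbl$rank, tbl$contig_id)
    for (r in ranks) expect_equal(r, seq_along(r) - 1L)
  }
})

test_that("impossible cis positions are a configuration error", {
  tmpl <- single_layout_template(
    core = c("narG", "narH"), chaperone = "narJ", cis_index = 5
  )
  expect_error(generate_genome(tmpl, seed = 1), "impossible layout")
})

test_that("a planted cis layout round-trips through classification", {
  tmpl <- single_layout_template(
    core = c("narG", "narH", "narI"), chaperone = "narJ", cis_index = 3,
    cis_prob = 1, flank_prob = 1
  )
  tbl <- generate_genome(tmpl, "GRT", seed = 4)
  res <- classify_associations(tbl)
  expect_equal(res$mode, "cis")
  expect_equal(res$flanked_by_prev, "narh")
  expect_equal(res$flanked_by_next, "nari")
})

test_that("a planted trans layout round-trips through classification", {
  tmpl <- single_layout_template(
    core = c("torA", "torC"), chaperone = "torD", cis_index = 3,
    cis_prob = 0, trans_prob = 1
  )
  tbl <- generate_genome(tmpl, "GTR", seed = 4)
  res <- classify_association(
    tbl, tbl$locus_tag[tbl$gene_name == "tord"],
    cism_definition("torD", list(torD_torAC = c("torA", "torC")))
  )
  expect_equal(res$mode, "trans")
  expect_equal(res$matched_set_label, "torD_torAC")
})

test_that("zero mutation rate returns the ancestor unchanged", {
  anc <- random_codons(50)
  cfg <- evolution_config(omega = 0.5, rate = 0)
  expect_identical(evolve_pair(anc, cfg), anc)
})

test_that("omega = 0 admits only synonymous change", {
  set.seed(12)
  anc <- random_codons(200)
  cfg <- evolution_config(omega = 0, rate = 1)
  desc <- evolve_pair(anc, cfg)
  expect_false(identical(desc, anc))
  aln <- aln_from_codons(a = anc, b = desc)
  p <- pairwise_dnds(aln, "a", "b")
  expect_equal(p$Nd, 0)
  expect_equal(p$dN, 0)
  expect_true(p$Sd > 0)
})

test_that("descendants are always stop-free", {
  set.seed(3)
  anc <- random_codons(100)
  code <- genetic_code()
  for (om in c(0.2, 1, 2)) {
    desc <- evolve_pair(anc, evolution_config(omega = om, rate = 2))
    expect_false(any(code[desc] == "*"))
  }
})

test_that("the synonymous share of substitutions rises as omega falls", {
  syn_share <- function(om, seed) {
    withr::with_seed(seed, {
      shares <- replicate(10, {
        anc <- random_codons(300)
        desc <- evolve_pair(anc, evolution_config(omega = om, rate = 0.5))
        aln <- aln_from_codons(a = anc, b = desc)
        p <- pairwise_dnds(aln, "a", "b")
        p$Sd / (p$Sd + p$Nd)
      })
      mean(shares)
    })
  }
  shares <- vapply(c(0.1, 0.5, 1), syn_share, numeric(1), seed = 88)
  expect_true(all(diff(shares) < 0))
})

test_that("conserved columns never change and the MSA width is the ancestor length", {
  ds <- generate_dataset(
    n_genomes = 6, seed = 14, n_codons = 120,
    conserved_columns = c(5, 50, 100)
  )
  expect_true(all(nchar(ds$msa) == 120)) # indel-free: exact alignment
  aln <- thread_codons(ds$msa, ds$cds)
  for (col in c(5, 50, 100)) {
    for (fam in unique(ds$groups$family)) {
      ids <- ds$groups$id[ds$groups$family == fam]
      expect_equal(length(unique(aln$codons[ids, col])), 1)
    }
  }
})

test_that("truth tables line up with annotated chaperone loci", {
  ds <- generate_dataset(n_genomes = 6, seed = 8)
  expect_setequal(ds$truth$locus_tag, ds$groups$id)
  genes <- ds$annotations
  for (i in seq_len(nrow(ds$truth))) {
    rec <- genes[genes$locus_tag == ds$truth$locus_tag[i], ]
    expect_equal(rec$gene_name, ds$truth$family[i])
  }
})
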