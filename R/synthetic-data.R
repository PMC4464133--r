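# Synthetic annotated genomes and codon evolution.
#
# The generator emulates the operon architectures the pipeline is built to
# analyse: chaperone genes placed cis inside (or trans away from, or absent
# from) their cognate enzyme operons, optional accessory genes, transposase
# insertions near chaperone loci, and chaperone coding sequences diverged
# from a family ancestor under a target dN/dS. Everything is deterministic
# under a fixed seed.

#' Describe one operon layout of a genome template
#'
#' @param core Gene symbols of the enzyme operon, in order.
#' @param chaperone Chaperone gene symbol, or `NULL` for a plain operon.
#' @param cis_index 1-based position of the chaperone in the final gene
#'   order when placed cis (e.g. 3 puts narJ between narH and narI in
#'   narG-narH-narJ-narI).
#' @param cis_prob,trans_prob Placement probabilities; the remainder is
#'   `absent` (chaperone present but cognate operon omitted).
#' @param flank_prob Probability that a cis placement uses `cis_index`;
#'   otherwise the chaperone is appended at the operon end (or prepended,
#'   if `cis_index` already is the end).
#' @param optional List of optional gene groups, each
#'   `list(symbols =, p_any =, p_both = NULL, where = "end"|"start")`:
#'   with probability `p_both` all symbols are added, with `p_any - p_both`
#'   exactly one (uniformly chosen), otherwise none.
#' @param transposase_prob Probability of inserting a transposase gene just
#'   outside the operon, within the chaperone's ORF radius.
#' @return An `operon_layout` list.
#' @export
operon_layout <- function(core, chaperone = NULL, cis_index = NULL,
                          cis_prob = 1, trans_prob = 0, flank_prob = 1,
                          optional = list(), transposase_prob = 0) {
  stopifnot(cis_prob >= 0, trans_prob >= 0, cis_prob + trans_prob <= 1)
  stopifnot(flank_prob >= 0, flank_prob <= 1)
  if (!is.null(chaperone) && is.null(cis_index)) {
    abort("a layout with a chaperone needs a cis_index")
  }
  structure(
    list(
      core = core, chaperone = chaperone, cis_index = cis_index,
      cis_prob = cis_prob, trans_prob = trans_prob, flank_prob = flank_prob,
      optional = optional, transposase_prob = transposase_prob
    ),
    class = "operon_layout"
  )
}

#' Describe a synthetic genome template
#'
#' @param phylum Phylum label stamped on the genome's group map.
#' @param layouts List of [operon_layout()]s.
#' @param gap_range Uniform intergenic gap (bp) inside operons; keep the
#'   maximum at or below the operon-calling `max_gap` (default 2-120).
#' @param spacer_range Uniform gap (bp) between operon blocks and filler
#'   genes; keep the minimum above `max_gap` so blocks form separate
#'   operons (default 300-2000).
#' @param n_filler Filler ("hypothetical protein") genes placed before each
#'   operon block.
#' @param gene_len_range Range of gene lengths in codons.
#' @return A `genome_template` list.
#' @export
genome_template <- function(phylum, layouts, gap_range = c(2, 120),
                            spacer_range = c(300, 2000), n_filler = 5,
                            gene_len_range = c(100, 500)) {
  structure(
    list(
      phylum = phylum, layouts = layouts, gap_range = gap_range,
      spacer_range = spacer_range, n_filler = n_filler,
      gene_len_range = gene_len_range
    ),
    class = "genome_template"
  )
}

#' Default genome templates
#'
#' Three templates (a Gram-negative gammaproteobacterium, a Gram-positive
#' actinobacterium and a euryarchaeon) mirroring reported operon
#' architectures and frequencies: narGHJI with narJ cis at 91.7 % and
#' sitting between narH and narI in 98 % of cis placements, narK/narU
#' transporters (at least one 57.7 %, both 21.9 %) and ppiC (52.3 %);
#' narZYWV with narU (98 %); dmsABC with dmsD after dmsC in Gram-negatives
#' (65 %) and before dmsA in Gram-positives (61 %) / Archaea (85 %), cis at
#' 80 %, with transposases near dmsD at 21 %; torACD with only a third of
#' torD loci retaining a torAC association; fdhGHI with DUF3305/DUF3306 and
#' hybA (60 %); nrfD-hybA-bisC; ycdX-ycdY and the hflC-mdaB YcdY variant.
#'
#' @return Named list of [genome_template()]s.
#' @export
default_genome_templates <- function() {
  nar_optional <- list(
    list(symbols = c("narK", "narU"), p_any = 0.577, p_both = 0.219, where = "start"),
    list(symbols = "ppiC", p_any = 0.523, p_both = NULL, where = "end")
  )
  narGHJI <- operon_layout(
    core = c("narG", "narH", "narI"), chaperone = "narJ", cis_index = 3,
    cis_prob = 0.917, trans_prob = 0.083, flank_prob = 0.98,
    optional = nar_optional
  )
  narZYWV <- operon_layout(
    core = c("narZ", "narY", "narV"), chaperone = "narW", cis_index = 3,
    cis_prob = 1, flank_prob = 1,
    optional = list(list(symbols = "narU", p_any = 0.98, p_both = NULL, where = "end"))
  )
  list(
    gammaproteobacteria = genome_template(
      phylum = "Gammaproteobacteria",
      layouts = list(
        narGHJI,
        narZYWV,
        operon_layout(
          core = c("dmsA", "dmsB", "dmsC"), chaperone = "dmsD", cis_index = 4,
          cis_prob = 0.80, trans_prob = 0.15, flank_prob = 0.65,
          transposase_prob = 0.21
        ),
        operon_layout(
          core = c("torA", "torC"), chaperone = "torD", cis_index = 3,
          cis_prob = 0.28, trans_prob = 0.05, flank_prob = 1
        ),
        operon_layout(
          core = "ycdX", chaperone = "ycdY", cis_index = 2,
          cis_prob = 0.9, trans_prob = 0.05, flank_prob = 1
        )
      )
    ),
    actinobacteria = genome_template(
      phylum = "Actinobacteria",
      layouts = list(
        narGHJI,
        operon_layout(
          core = c("dmsA", "dmsB", "dmsC"), chaperone = "dmsD", cis_index = 1,
          cis_prob = 0.80, trans_prob = 0.15, flank_prob = 0.61,
          transposase_prob = 0.21
        ),
        operon_layout(
          core = c("fdhG", "fdhH", "fdhI"), chaperone = "torD", cis_index = 1,
          cis_prob = 0.9, trans_prob = 0.05, flank_prob = 1,
          optional = list(list(
            symbols = c("DUF3305", "DUF3306", "hybA"),
            p_any = 0.60, p_both = 0.60, where = "start"
          ))
        ),
        operon_layout(
          core = c("hflC", "mdaB"), chaperone = "ycdY", cis_index = 3,
          cis_prob = 0.9, trans_prob = 0, flank_prob = 1
        )
      )
    ),
    euryarchaeota = genome_template(
      phylum = "Euryarchaeota",
      layouts = list(
        narGHJI,
        operon_layout(
          core = c("dmsA", "dmsB", "dmsC"), chaperone = "dmsD", cis_index = 1,
          cis_prob = 0.80, trans_prob = 0.15, flank_prob = 0.85,
          transposase_prob = 0.21
        ),
        operon_layout(
          core = c("nrfD", "hybA", "bisC"), chaperone = "torD", cis_index = 4,
          cis_prob = 0.9, trans_prob = 0, flank_prob = 1
        )
      )
    )
  )
}

.product_for <- function(symbol) {
  known <- c(
    narG = "nitrate reductase alpha subunit",
    narH = "nitrate reductase beta subunit",
    narI = "nitrate reductase gamma subunit",
    narJ = "nitrate reductase molybdenum cofactor assembly chaperone",
    narZ = "nitrate reductase 2 alpha subunit",
    narY = "nitrate reductase 2 beta subunit",
    narV = "nitrate reductase 2 gamma subunit",
    narW = "nitrate reductase 2 chaperone",
    narK = "nitrate/nitrite MFS transporter",
    narU = "nitrate/nitrite MFS transporter",
    ppiC = "parvulin-like peptidyl-prolyl isomerase",
    dmsA = "DMSO reductase alpha subunit",
    dmsB = "DMSO reductase iron-sulfur subunit",
    dmsC = "DMSO reductase membrane anchor subunit",
    dmsD = "twin-arginine leader-binding chaperone DmsD",
    torA = "TMAO reductase catalytic subunit",
    torC = "TMAO reductase c-type cytochrome",
    torD = "TMAO reductase system chaperone TorD",
    ycdX = "zinc-binding phosphoesterase YcdX",
    ycdY = "chaperone protein YcdY",
    hflC = "protease modulator HflC",
    mdaB = "NADPH quinone reductase MdaB",
    fdhG = "formate dehydrogenase subunit G",
    fdhH = "formate dehydrogenase iron-sulfur subunit",
    fdhI = "formate dehydrogenase gamma subunit",
    nrfD = "polysulfide reductase membrane component NrfD",
    hybA = "hydrogenase 4Fe-4S ferredoxin-type component",
    bisC = "biotin sulfoxide reductase family molybdoenzyme",
    DUF3305 = "membrane protein of unknown function DUF3305",
    DUF3306 = "membrane protein of unknown function DUF3306"
  )
  out <- unname(known[symbol])
  ifelse(is.na(out), paste(symbol, "family protein"), out)
}

.resolve_optional <- function(opt) {
  p_both <- opt$p_both
  if (is.null(p_both)) p_both <- if (length(opt$symbols) > 1) 0 else opt$p_any
  u <- runif(1)
  if (length(opt$symbols) == 1) {
    if (u < opt$p_any) opt$symbols else character(0)
  } else if (u < p_both) {
    opt$symbols
  } else if (u < opt$p_any) {
    sample(opt$symbols, 1)
  } else {
    character(0)
  }
}

#' Generate one annotated synthetic genome
#'
#' Lays the template's operon blocks on a single contig with filler genes in
#' between. Within a block, genes share a strand and are separated by gaps
#' drawn from `gap_range`; blocks, fillers and trans-placed chaperones are
#' separated by spacer gaps larger than typical operon-calling `max_gap`
#' values, and trans chaperones are additionally padded by 12 filler genes
#' so they fall outside a 10-ORF radius of their cognate operon.
#'
#' @param template A [genome_template()].
#' @param genome_id Genome identifier.
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output.
#' @return Canonical annotation tibble with a `truth` attribute recording,
#'   per chaperone locus, the placement drawn (`cis`/`trans`/`absent`),
#'   whether the cis placement used `cis_index` (`at_cis_index`), and the
#'   transposase flag.
#' @export
generate_genome <- function(template, genome_id = "G1", seed = NULL) {
  run <- function() .generate_genome_impl(template, genome_id)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

.generate_genome_impl <- function(template, genome_id) {
  for (ly in template$layouts) {
    if (!is.null(ly$chaperone) && ly$cis_index > length(ly$core) + 1) {
      abort(paste0(
        "impossible layout: cis position ", ly$cis_index,
        " beyond operon length for chaperone ", ly$chaperone
      ))
    }
  }
  filler_unit <- function() {
    tibble(gene_name = "", product = "hypothetical protein", own_strand = TRUE)
  }
  units <- list() # each unit: tibble(gene_name, product, own_strand)
  truth <- list()
  for (ly in template$layouts) {
    u <- runif(1)
    placement <- if (u < ly$cis_prob) {
      "cis"
    } else if (u < ly$cis_prob + ly$trans_prob) "trans" else "absent"
    if (is.null(ly$chaperone)) placement <- "none"
    genes <- ly$core
    for (opt in ly$optional) {
      add <- .resolve_optional(opt)
      genes <- if (identical(opt$where, "start")) c(add, genes) else c(genes, add)
    }
    at_cis_index <- NA
    chap_sym <- ly$chaperone
    if (placement == "cis") {
      # cis_index counts positions in the core+chaperone order; optional
      # genes prepended at the operon start shift it right
      start_syms <- unlist(lapply(
        Filter(function(o) identical(o$where, "start"), ly$optional),
        function(o) o$symbols
      ))
      n_start <- sum(genes %in% start_syms)
      at_cis_index <- runif(1) < ly$flank_prob
      pos <- if (at_cis_index) {
        ly$cis_index + n_start
      } else if (ly$cis_index + n_start > length(genes)) {
        1L # fallback: prepend when the canonical slot is the operon end
      } else {
        length(genes) + 1L # fallback: append at the operon end
      }
      genes <- append(genes, chap_sym, after = pos - 1L)
    }
    include_block <- placement != "absent"
    if (include_block) {
      block <- tibble(
        gene_name = genes,
        product = .product_for(genes),
        own_strand = FALSE
      )
      # fillers ahead of the block, then the block
      for (k in seq_len(template$n_filler)) units[[length(units) + 1]] <- filler_unit()
      units[[length(units) + 1]] <- block
      transposase_here <- placement == "cis" && runif(1) < ly$transposase_prob
      if (transposase_here) {
        units[[length(units) + 1]] <- tibble(
          gene_name = "",
          product = "IS5 family transposase",
          own_strand = TRUE
        )
      }
    } else {
      transposase_here <- FALSE
    }
    if (placement %in% c("trans", "absent")) {
      # pad with 12 fillers so the chaperone is outside a 10-ORF radius of
      # any operon block, then the lone chaperone
      for (k in 1:12) units[[length(units) + 1]] <- filler_unit()
      units[[length(units) + 1]] <- tibble(
        gene_name = chap_sym,
        product = .product_for(chap_sym),
        own_strand = TRUE
      )
      if (runif(1) < ly$transposase_prob) {
        units[[length(units) + 1]] <- tibble(
          gene_name = "",
          product = "IS5 family transposase",
          own_strand = TRUE
        )
        transposase_here <- TRUE
      }
    }
    if (!is.null(chap_sym)) {
      truth[[length(truth) + 1]] <- tibble(
        genome_id = genome_id,
        family = tolower(chap_sym),
        placement = placement,
        at_cis_index = at_cis_index,
        transposase = transposase_here
      )
    }
  }
  for (k in 1:12) units[[length(units) + 1]] <- filler_unit()

  rows <- list()
  pos <- 1L
  locus_i <- 0L
  for (un in units) {
    block_strand <- sample(c("+", "-"), 1)
    pos <- pos + as.integer(round(runif(1, template$spacer_range[1], template$spacer_range[2])))
    for (r in seq_len(nrow(un))) {
      if (r > 1) {
        pos <- pos + as.integer(round(runif(1, template$gap_range[1], template$gap_range[2])))
      }
      len <- 3L * sample(template$gene_len_range[1]:template$gene_len_range[2], 1)
      locus_i <- locus_i + 1L
      rows[[length(rows) + 1]] <- tibble(
        genome_id = genome_id,
        contig_id = paste0(genome_id, "_c1"),
        locus_tag = sprintf("%s_%05d", genome_id, locus_i * 5L),
        gene_name = un$gene_name[r],
        product = un$product[r],
        start = pos,
        end = pos + len - 1L,
        strand = if (un$own_strand[r]) sample(c("+", "-"), 1) else block_strand
      )
      pos <- pos + len
    }
  }
  tbl <- as_annotation(bind_rows(rows))
  truth <- bind_rows(truth)
  # attach the locus tag of each chaperone gene to the truth table
  truth$locus_tag <- vapply(seq_len(nrow(truth)), function(i) {
    hits <- tbl$locus_tag[tbl$gene_name == truth$family[i]]
    hits[sum(truth$family[seq_len(i)] == truth$family[i])]
  }, character(1))
  attr(tbl, "truth") <- truth
  tbl
}

#' Configuration of the codon-evolution process
#'
#' @param omega Target dN/dS (> 0).
#' @param rate Expected proposed single-nucleotide changes per codon along
#'   one lineage.
#' @param length Sequence length in codons.
#' @param conserved_columns Codon positions protected from change (used to
#'   plant fully conserved motif columns).
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(omega, rate = 0.5, length = 300,
                             conserved_columns = integer(0)) {
  stopifnot(omega >= 0, rate >= 0, length >= 1)
  structure(
    list(
      omega = omega, rate = rate, length = as.integer(length),
      conserved_columns = as.integer(conserved_columns)
    ),
    class = "evolution_config"
  )
}

#' Random stop-free codon sequence
#'
#' @param n Length in codons.
#' @return Character vector of `n` sense codons starting with ATG.
#' @export
random_codons <- function(n) {
  sense <- setdiff(.sense_codons(), "ATG")
  c("ATG", sample(sense, n - 1, replace = TRUE))
}

#' Evolve a codon sequence under a target dN/dS
#'
#' Proposes `Poisson(rate x length)` single-nucleotide changes at uniformly
#' chosen positions. Proposals creating a stop codon are rejected. For
#' `omega <= 1` synonymous proposals are always accepted and non-synonymous
#' ones with probability `omega`; for `omega > 1` the scheme is inverted
#' (non-synonymous always, synonymous with probability `1/omega`), so the
#' realized non-synonymous/synonymous rate ratio per site is `omega` in both
#' regimes. Positions in `conserved_columns` never change.
#'
#' @param codons Character vector of sense codons (the ancestor).
#' @param cfg An [evolution_config()] (its `length` field is ignored here).
#' @return The descendant codon vector, stop-free by construction.
#' @export
evolve_pair <- function(codons, cfg) {
  code <- genetic_code()
  n <- length(codons)
  n_prop <- rpois(1, cfg$rate * n)
  if (n_prop == 0) {
    return(codons)
  }
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_prop)) {
    j <- sample.int(n, 1)
    if (j %in% cfg$conserved_columns) next
    p <- sample.int(3, 1)
    cur <- codons[j]
    cur_chars <- strsplit(cur, "")[[1]]
    alt <- sample(setdiff(bases, cur_chars[p]), 1)
    mut_chars <- cur_chars
    mut_chars[p] <- alt
    mut <- paste(mut_chars, collapse = "")
    if (code[mut] == "*") next
    syn <- code[mut] == code[cur]
    p_acc <- if (cfg$omega <= 1) {
      if (syn) 1 else cfg$omega
    } else {
      if (syn) 1 / cfg$omega else 1
    }
    if (runif(1) < p_acc) codons[j] <- mut
  }
  codons
}

#' Generate a full synthetic dataset
#'
#' Generates `n_genomes` annotated genomes (templates used round-robin),
#' evolves each chaperone coding sequence from a per-family random ancestor
#' under the family's target dN/dS, and returns the matching protein MSA,
#' CDS set and group map in exactly the dialects the analysis functions
#' consume. The simulation is indel-free, so the protein MSA is exact by
#' construction (width = ancestor length) and no aligner is involved.
#'
#' @param n_genomes Number of genomes.
#' @param templates Named list of [genome_template()]s
#'   (default [default_genome_templates()]).
#' @param omega Named numeric vector of target dN/dS per chaperone family;
#'   defaults to the reported subfamily means
#'   (narJ 0.65, narW 0.65, dmsD 0.57, torD 0.65, ycdY 0.24).
#' @param rate Expected proposed changes per codon per lineage (ancestor to
#'   tip).
#' @param n_codons Chaperone gene length in codons.
#' @param conserved_columns Codon positions kept invariant in every family
#'   (planted conserved motif columns).
#' @param seed Integer seed; the whole dataset is deterministic under it.
#' @return List with `annotations` (bound canonical tibble), `truth`
#'   (placement ground truth), `msa` (named aligned protein vector), `cds`
#'   (named CDS vector, with terminal stop codons), and `groups`
#'   (tibble `id, family, phylum, genome_id`).
#' @export
generate_dataset <- function(n_genomes = 20,
                             templates = default_genome_templates(),
                             omega = c(
                               narj = 0.65, narw = 0.65, dmsd = 0.57,
                               tord = 0.65, ycdy = 0.24
                             ),
                             rate = 0.5, n_codons = 300,
                             conserved_columns = integer(0),
                             seed = 1) {
  names(omega) <- tolower(names(omega))
  withr::with_seed(seed, {
    fams <- unique(tolower(unlist(lapply(templates, function(t) {
      vapply(
        Filter(function(l) !is.null(l$chaperone), t$layouts),
        function(l) l$chaperone, character(1)
      )
    }))))
    ancestors <- setNames(lapply(fams, function(f) random_codons(n_codons)), fams)
    annotations <- list()
    truths <- list()
    msa <- character(0)
    cds <- character(0)
    groups <- list()
    code <- genetic_code()
    for (g in seq_len(n_genomes)) {
      tmpl <- templates[[(g - 1) %% length(templates) + 1]]
      gid <- sprintf("SYN%03d", g)
      tbl <- .generate_genome_impl(tmpl, gid)
      tr <- attr(tbl, "truth")
      annotations[[g]] <- tbl
      truths[[g]] <- tr
      for (i in seq_len(nrow(tr))) {
        fam <- tr$family[i]
        if (is.na(omega[fam])) next
        cfg <- evolution_config(
          omega = unname(omega[fam]), rate = rate,
          conserved_columns = conserved_columns
        )
        desc <- evolve_pair(ancestors[[fam]], cfg)
        id <- tr$locus_tag[i]
        msa[id] <- paste(unname(code[desc]), collapse = "")
        cds[id] <- paste(c(desc, "TAA"), collapse = "")
        groups[[length(groups) + 1]] <- tibble(
          id = id, family = fam, phylum = tmpl$phylum, genome_id = gid
        )
      }
    }
    list(
      annotations = bind_rows(annotations),
      truth = bind_rows(truths),
      msa = msa,
      cds = cds,
      groups = bind_rows(groups)
    )
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits the dataset in the file dialects the pipeline consumes: one GFF3
#' per genome, `annotations.tsv`, `msa.faa`, `cds.fna` and `groups.tsv`.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in unique(dataset$annotations$genome_id)) {
    write_annotation(
      dataset$annotations[dataset$annotations$genome_id == g, ],
      file.path(dir, paste0(g, ".gff3")),
      dialect = "gff3"
    )
  }
  write_annotation(dataset$annotations, file.path(dir, "annotations.tsv"), "tsv")
  write_fasta(dataset$msa, file.path(dir, "msa.faa"))
  write_fasta(dataset$cds, file.path(dir, "cds.fna"))
  readr::write_tsv(dataset$groups, file.path(dir, "groups.tsv"), progress = FALSE)
  invisible(dir)
}
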