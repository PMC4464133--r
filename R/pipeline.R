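# End-to-end orchestration: annotations -> neighborhoods -> operon
# association -> gene frequencies -> dN/dS -> motifs -> presence
# correlations, with a reproducible run manifest.

#' Build a pipeline configuration
#'
#' @param annotations Path(s) to annotation files (GFF3 or the TSV dialect),
#'   or a directory containing them.
#' @param msa Path to the aligned protein FASTA of chaperone homologues.
#' @param cds Path to the matching unaligned CDS FASTA.
#' @param groups Path to the group map TSV (`id, family, phylum`).
#' @param definitions Path to a YAML/JSON chaperone-family definition file,
#'   or `NULL` for [default_cism_definitions()].
#' @param out_dir Output directory for the report bundle.
#' @param radius ORF radius for neighborhoods (default 10).
#' @param max_gap Operon-calling intergenic gap in bp (default 150).
#' @param t1,t2 Motif identity tiers (defaults 0.60 / 0.75).
#' @param reference_id Reference sequence for motif numbering (default: the
#'   first MSA sequence).
#' @param homology_evalue Provenance note only: the e-value cutoff used when
#'   the input homologue set was assembled. Recorded in the manifest, never
#'   executed.
#' @param seed Integer seed recorded in the manifest and used for any
#'   randomized stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(annotations, msa, cds, groups,
                            definitions = NULL, out_dir = "rempscan-out",
                            radius = 10, max_gap = 150,
                            t1 = 0.60, t2 = 0.75, reference_id = NULL,
                            homology_evalue = 1e-4, seed = 1) {
  stopifnot(radius >= 1, t1 >= 0, t1 < t2, t2 <= 1)
  structure(
    list(
      annotations = annotations, msa = msa, cds = cds, groups = groups,
      definitions = definitions, out_dir = out_dir, radius = radius,
      max_gap = max_gap, t1 = t1, t2 = t2, reference_id = reference_id,
      jc_cutoff = 0.75, homology_evalue = homology_evalue, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes a report bundle to `cfg$out_dir`:
#' `associations.tsv`, `gene_frequency.tsv`, `dnds_pairs.tsv`,
#' `dnds_summary.tsv`, `sd_profile.tsv`, `motifs.tsv`,
#' `presence_correlation.tsv` and `manifest.json` (package version, config,
#' seed and input checksums). Re-running with identical inputs and seed
#' reproduces the bundle bit for bit.
#'
#' @param cfg A [pipeline_config()] or path to a YAML config.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::local_seed(cfg$seed)

  ann_paths <- cfg$annotations
  if (length(ann_paths) == 1 && dir.exists(ann_paths)) {
    ann_paths <- list.files(ann_paths, pattern = "\\.(gff3?|tsv)$", full.names = TRUE)
  }
  genes <- .stage("annotation", {
    bind_rows(lapply(ann_paths, function(p) {
      read_annotation(p, dialect = if (grepl("\\.gff3?$", p)) "gff3" else "tsv")
    }))
  })
  defs <- .stage("definitions", {
    if (is.null(cfg$definitions)) {
      default_cism_definitions()
    } else {
      read_cism_definitions(cfg$definitions)
    }
  })
  assoc <- .stage("association", {
    classify_associations(genes, defs, max_gap = cfg$max_gap, radius = cfg$radius)
  })
  write_report(select(assoc, -"evidence"), file.path(cfg$out_dir, "associations.tsv"), "tsv")

  freq <- .stage("gene_frequency", {
    purrr::map_dfr(names(defs), function(fam) {
      loci <- genes$locus_tag[genes$gene_name == fam]
      if (!length(loci)) {
        return(NULL)
      }
      nb <- extract_neighborhoods(genes, loci, radius = cfg$radius)
      symbols <- sort(unique(c(
        unlist(defs[[fam]]$sets),
        setdiff(unique(nb$gene_name[nb$gene_name != ""]), fam)
      )))
      ops <- assign_operons(genes, cfg$max_gap)
      n_op <- dplyr::n_distinct(ops$operon_id[ops$locus_tag %in% loci])
      gene_frequency(nb, n_op, symbols) %>%
        mutate(family = fam, .before = 1)
    })
  })
  write_report(freq, file.path(cfg$out_dir, "gene_frequency.tsv"), "tsv")

  msa <- .stage("msa", read_msa(cfg$msa))
  groups <- .stage("groups", {
    readr::read_tsv(cfg$groups, show_col_types = FALSE, progress = FALSE)
  })
  aln <- .stage("dnds", {
    cds <- read_cds(cfg$cds, ids = names(msa))
    thread_codons(msa, cds)
  })
  pairs <- .stage("dnds", dnds_pairs(aln, groups, within = c("family", "phylum")))
  write_report(pairs, file.path(cfg$out_dir, "dnds_pairs.tsv"), "tsv")
  summ <- .stage("dnds", group_summary(pairs))
  write_report(summ, file.path(cfg$out_dir, "dnds_summary.tsv"), "tsv")
  sdp <- .stage("sd_profile", {
    purrr::map_dfr(split(groups$id, groups$family), function(ids) {
      ids <- intersect(ids, aln$ids)
      if (length(ids) < 2) {
        return(NULL)
      }
      sd_profile(aln, ids)
    }, .id = "family")
  })
  write_report(sdp, file.path(cfg$out_dir, "sd_profile.tsv"), "tsv")

  motifs <- .stage("motif", {
    ref <- cfg$reference_id %||% names(msa)[1]
    overall <- extract_motif(identity_profile(msa), msa, ref, cfg$t1, cfg$t2) %>%
      mutate(subgroup = "all", .before = 1)
    per_fam <- purrr::map_dfr(split(groups$id, groups$family), function(ids) {
      ids <- intersect(ids, names(msa))
      if (length(ids) < 2) {
        return(NULL)
      }
      fam_ref <- if (ref %in% ids) ref else ids[1]
      extract_motif(identity_profile(msa, ids), msa, fam_ref, cfg$t1, cfg$t2)
    }, .id = "subgroup")
    bind_rows(overall, per_fam)
  })
  write_report(motifs, file.path(cfg$out_dir, "motifs.tsv"), "tsv")

  corr <- .stage("presence_correlation", {
    pm <- presence_matrix(genes, defs)
    if (nrow(pm) >= 2 && ncol(pm) >= 3) presence_correlation(pm) else NULL
  })
  if (!is.null(corr)) {
    write_report(
      tibble(column = rownames(corr)) %>%
        bind_cols(as_tibble(as.data.frame(unclass(corr)))),
      file.path(cfg$out_dir, "presence_correlation.tsv"), "tsv"
    )
  }

  manifest <- list(
    package = "rempscan",
    version = as.character(utils::packageVersion("rempscan")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    inputs = lapply(
      setNames(nm = c(ann_paths, cfg$msa, cfg$cds, cfg$groups)),
      function(p) unname(tools::md5sum(p))
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(list(
    genes = genes, associations = assoc, gene_frequency = freq,
    dnds_pairs = pairs, dnds_summary = summ, sd_profile = sdp,
    motifs = motifs, presence_correlation = corr
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
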