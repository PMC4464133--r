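# rempscan

Comparative-genomic analysis of **redox enzyme maturation protein (REMP)
chaperones** of the NarJ subfamily (NarJ, NarW, DmsD, TorD, YcdY) and their
cognate **complex iron–sulfur molybdoenzyme (CISM)** operons — membrane-bound
nitrate reductases (narGHI, narZYV), DMSO/selenate reductases
(dmsABC, ynfEFGH), TMAO reductase (torAC), formate dehydrogenase (fdhGHI)
and related systems. These chaperones bind the twin-arginine (TAT) signal
peptide of their target enzyme and coordinate cofactor loading before
export, so where a chaperone gene sits relative to its enzyme operon, how
strongly its codons are constrained, and which residues its subfamily
conserves are all informative about chaperone–enzyme coevolution.

The package is for microbial comparative genomicists who have annotated
genomes and a curated protein alignment of chaperone homologues, and want a
reproducible, tested pipeline for three linked questions:

1. **Operon association.** For each chaperone locus, is it *cis* (inside its
   cognate CISM operon), *trans* (elsewhere in a genome that still carries
   the complete operon) or *absent*? Neighborhoods are counted in ORFs
   (default ±10 genes), operons are called as maximal same-strand runs with
   intergenic gaps ≤ 150 bp, and gene co-occurrence around chaperone loci is
   summarised by the frequency-of-gene-occurrence statistic

   F^G = (n^gene / n^locus) / O,

   where n^gene counts loci whose ±10-ORF radius contains the gene,
   n^locus the loci examined and O the chaperone operons examined (the raw
   fraction n^gene/n^locus is reported alongside, since architecture
   percentages correspond to it). Presence/absence of whole systems across
   genomes is correlated with phi coefficients.

2. **Codon-level selection.** CDS sequences are threaded onto the protein
   alignment (genetic code 11) and every intra-subgroup pair is scored by
   Nei–Gojobori counting: pathway-averaged synonymous/non-synonymous
   differences Sd and Nd, site counts S and N, proportions pS = Sd/S and
   pN = Nd/N, Jukes–Cantor correction d = −(3/4)ln(1 − 4p/3) (undefined at
   the saturation cutoff pS ≥ 0.75), and the ratio ω = dN/dS. Groups
   (family × phylum) are summarised by five-number percentile summaries, and
   per-codon Sd profiles localise synonymous divergence along the gene.

3. **Consensus motifs.** Per-column identity profiles over any subgroup
   yield two-tier motifs — normal (identity 60–75 %) and bold (≥ 75 %) —
   numbered against a reference sequence (insertion positions get suffixes
   like `84a`), with motif-to-motif comparison in `K37G` substitution
   notation.

A bundled synthetic-genome and codon-evolution generator reproduces the
operon architectures and divergence regimes the pipeline expects, so every
stage is testable end to end without downloads.

## Worked example

```r
library(rempscan)

ds <- generate_dataset(n_genomes = 6, seed = 42)   # synthetic genomes + sequences
assoc <- classify_associations(ds$annotations)
dplyr::count(assoc, family, mode)
#>   family mode       n
#> 1 dmsd   cis        5
#> 2 dmsd   trans      1
#> 3 narj   cis        6
#> 4 narw   cis        2
#> 5 tord   absent     1
#> 6 tord   cis        4
#> 7 tord   trans      1
#> 8 ycdy   absent     1
#> 9 ycdy   cis        3
```

All six narJ loci are cis — the generator's default templates place narJ
inside narGHI at the reported 91.7 % rate — while torD shows the mixed
cis/trans/absent pattern typical of TMAO reductase chaperones.

```r
aln   <- thread_codons(ds$msa, ds$cds)
pairs <- dnds_pairs(aln, ds$groups, within = c("family", "phylum"))
group_summary(pairs)
#>    family phylum              n_pairs   median ...
#>  1 dmsd   Actinobacteria            1   0.660
#>  5 narj   Euryarchaeota             1   0.508
#> 11 ycdy   Actinobacteria            1   0.336
#> 12 ycdy   Gammaproteobacteria       1   0.296
autoplot(group_summary(pairs))   # box-style dN/dS panel per family x phylum
```

Every median sits below 1 (purifying selection), and ycdY — simulated at
the strongest constraint, target ω = 0.24 — is clearly the most conserved.

```r
ids   <- ds$groups$id[ds$groups$family == "narj"]
motif <- extract_motif(identity_profile(ds$msa, ids), ds$msa, ids[1])
head(motif, 3)
#>   column ref_label residue identity tier
#> 1      1         1       M    0.667 normal
#> 2      2         2       A    1     bold
#> 3      5         5       Q    0.833 bold
```

For file-based work, `run_pipeline(pipeline_config(...))` executes all
stages from GFF3/TSV + FASTA inputs and writes a TSV/JSON report bundle
with a checksummed manifest; `inst/cli/rempscan.R` is a thin command-line
wrapper over the same functions.

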