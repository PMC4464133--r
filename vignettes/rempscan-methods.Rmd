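---
title: "Methods: operon association, codon-level selection and consensus motifs for REMP chaperones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operon association, codon-level selection and consensus motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rempscan)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the parameters that matter, and the design
choices made where the methodology was genuinely open. The system under
study is the NarJ subfamily of redox enzyme maturation protein (REMP)
chaperones — NarJ, NarW, DmsD, TorD and YcdY — and their cognate complex
iron–sulfur molybdoenzyme (CISM) operons in bacteria and archaea.

## Gene neighborhoods and operon calls

A chaperone locus is characterised by its ±`radius` **ORF neighborhood**:
the `radius` annotated genes on each side by gene index (rank) on the same
contig, regardless of strand or base-pair distance, truncated at contig
ends. The default radius of 10 genes is wide enough to span any of the
CISM operon architectures handled here plus flanking accessory genes.

**Operon calls** use the standard prokaryotic distance heuristic: maximal
runs of same-strand genes whose successive intergenic gaps are at most
`max_gap` (default 150 bp, the usual operon-prediction threshold).
Annotation pipelines rarely record operon boundaries explicitly, and where
curators decide membership by inspection no single rule reproduces every
call; the gap rule is a transparent, configurable stand-in, and every gene
belongs to exactly one call, so the segmentation is a partition — a
property the test suite asserts.

**Gene identity matching** for cognate genes tries the annotated gene
symbol first and falls back to a case-insensitive substring match against
the product description, because chaperone and enzyme genes are
inconsistently named across genomes (e.g. a *dmsD* annotated only as
"twin-arginine leader-binding chaperone").

## cis / trans / absent classification

A chaperone locus is **cis** when at least one gene of any cognate set
shares its operon call. Requiring only one gene, not the complete set, is
deliberate: incomplete operons (e.g. DMSO reductase operons lacking the
membrane-anchor subunit *dmsC*) still represent a genuine genetic
association. It is **trans** when no cognate gene is co-operonic but at
least one cognate set is *completely* present elsewhere in the genome —
completeness guards against declaring an association to a system the
genome does not actually encode — and **absent** otherwise. When several
cognate sets match, the set with the largest overlap with the focal operon
wins, with ties broken by the definition file's set order, so results are
deterministic. Neighborhoods containing a product matching
`transposase|integrase|insertion sequence` are flagged, since mobile
elements near a chaperone locus suggest lateral transfer of the operon.

The **frequency of gene occurrence** is
`F_G = (n_gene / n_locus) / O`: a per-locus co-occurrence fraction divided
by the number of chaperone operons examined. Because the division by `O`
gives `F_G` non-intuitive units, the raw fraction `n_gene / n_locus` is
always reported next to it; co-occurrence percentages for architecture
summaries (e.g. "≥ 80 % co-frequency") correspond to the raw fraction. A
gene present twice in one neighborhood counts once — the statistic counts
loci, not occurrences.

**Presence/absence correlations** across genomes are phi coefficients
(Pearson correlation of binary columns), computed from the 2×2 contingency
counts. Constant columns have no defined correlation and are reported as
`NA`, never coerced to zero.

## Codon alignment and pairwise dN/dS

CDS sequences are threaded codon-by-codon onto the protein alignment under
NCBI genetic code 11 (fixed; the organisms are prokaryotes). Threading
validates length (after trimming one terminal stop), translation agreement
and absence of internal stops, and errors name the sequence and offset.

Pairwise divergence uses Nei–Gojobori counting:

* **Sites.** For each codon position, the fraction of the three
  single-nucleotide mutants that are synonymous, computed over non-stop
  mutants only, so S + N = 3 exactly per codon. Site counts for a pair are
  the average of the two sequences' counts.
* **Differences.** For codons differing at k ≤ 3 positions, synonymous and
  non-synonymous steps are averaged with equal weight over all k!
  orderings; orderings that pass through a stop codon are excluded and the
  remainder re-weighted. Sd + Nd always equals the raw nucleotide
  difference count. In the (not observed among sense-codon pairs, but
  handled) degenerate case where every ordering is blocked, each position
  is classified independently in both codon contexts and the pair is
  flagged. Equal pathway weighting is the original convention; no
  transition/transversion weighting is applied (a documented non-goal).
* **Distances.** pS = Sd/S and pN = Nd/N are corrected for multiple hits
  with Jukes–Cantor, d = −(3/4)ln(1 − 4p/3), undefined for p ≥ 0.75. A
  pair is **invalid** when pS or pN reaches that saturation cutoff, when no
  synonymous sites were compared, or when dS = 0 (identical pairs give an
  undefined 0/0 ratio; dS = 0 with dN > 0 is reported as `Inf` but excluded
  from percentile summaries, which must stay bounded). Applying the cutoff
  to pN as well as pS keeps the validity rule symmetric.
* **Gaps and ambiguity.** Any codon column where either sequence has a gap
  or a non-ACGT base is skipped for that pair (pairwise deletion),
  matching pairwise-comparison semantics; alignment-wide deletion would
  discard columns for all pairs because of one ragged sequence.

Comparisons are made only within subgroups (same family, and same phylum
for the grouped summaries) — cross-family ratios would mix homologous but
functionally diverged proteins. Group summaries are five-number percentile
summaries using linear interpolation between order statistics
(`quantile` type 7), with invalid pairs tallied separately. Per-column
**Sd profiles** report the mean pathway-averaged Sd over contributing
pairs per codon column; means are the default (a `sum` option exists), and
the weighted column means reconcile exactly (tolerance 1e-9) with the mean
per-pair total.

## Consensus motifs

Per-column identity is the frequency of the modal residue, with ties
broken alphabetically for determinism. Gaps count in the denominator by
default, so a mostly-gapped column can never look conserved — appropriate
after poorly aligned regions have been trimmed; a `count_gaps = FALSE`
mode divides by the non-gap count instead, since alignment viewers differ
on this convention. Motifs keep columns at identity ≥ 0.60 in two tiers:
*normal* `[0.60, 0.75)` and *bold* `[0.75, 1]`. Tier bounds are often
quoted as "60–74 %" and ">75 %", which leaves 74–75 % unassigned; the
half-open partition used here assigns every emitted column to exactly one
tier and treats exactly-75 % columns as bold. Positions are numbered by the running count
of non-gap reference residues; columns where the reference is gapped take
the preceding number plus an insertion suffix (`84a`, `84b`), the standard
reference-numbering practice. Raising either threshold can only remove
entries (monotonicity, property-tested).

## The synthetic-data generator

The generator exists so the whole pipeline can be exercised end to end
with known ground truth. Its defaults *are* the study conditions the
package targets:

* **Architectures.** narGHJI (narJ cis at 91.7 %, between narH and narI in
  98 % of cis placements, narK/narU transporters at 57.7 % at-least-one /
  21.9 % both, ppiC at 52.3 %); narZYWV (narW always cis, narU 98 %);
  dmsABC with dmsD after dmsC in Gram-negatives (65 %) and before dmsA in
  Gram-positives (61 %) and archaea (85 %), cis at 80 %, transposases near
  dmsD at 21 %; torACD with roughly a third of torD loci retaining a torAC
  association; fdhGHI with DUF3305/DUF3306/hybA (60 %); nrfD–hybA–bisC;
  ycdX–ycdY and the hflC–mdaB YcdY variant. Three templates
  (Gammaproteobacteria, Actinobacteria, Euryarchaeota) carry these layouts.
* **Geometry.** Operon genes share a strand with intra-operon gaps of
  2–120 bp; blocks, fillers and trans-placed chaperones are separated by
  300–2000 bp spacers (always above the 150 bp calling threshold), and
  trans chaperones are padded by 12 filler genes so they fall outside a
  10-ORF radius of their cognate operon. Gene lengths are 300–1500 bp.
* **Codon evolution.** Chaperone CDS are evolved from a random stop-free
  family ancestor by proposing `Poisson(rate × length)` single-nucleotide
  changes; proposals to stops are rejected, synonymous proposals accepted,
  non-synonymous accepted with probability ω (inverted for ω > 1), so the
  realized rate ratio per site is ω. Default family targets echo the
  purifying regimes typical of these chaperones (narJ/narW/torD 0.65,
  dmsD 0.57, ycdY 0.24); the default proposal rate of 0.5 per codon per
  lineage gives moderate divergence, well below the pS = 0.75 saturation.
  `conserved_columns` masks chosen codons from change, planting fully
  conserved motif columns for recovery tests.
* **Determinism.** All randomness flows through R's RNG under
  `withr::with_seed`; identical seeds give byte-identical datasets.

The default run is indel-free, so the emitted protein MSA is exact by
construction and no aligner enters the test loop. What the generator does
**not** emulate: phylogenetic tree structure among genomes (tips are
independent draws from the family ancestor), transition/transversion and
codon-usage bias, rate variation among sites (beyond planted invariant
columns), realistic intergenic composition, and annotation noise such as
miscalled or missing genes. Passing tests therefore demonstrate that the
statistics recover the parameters of this idealised process — not that
real annotations are free of the curation problems (mis-annotated *torD*
vs *dmsD*, duplicated *dmsA*) that real surveys must resolve by hand.

## Numerical choices and degenerate inputs

Conservation identities are asserted to 1e-9 (pathway averaging is exact
rational arithmetic in floating point at this scale). `jc_correct`
returns `NA` rather than raising at saturation, so one saturated pair
never aborts a batch; downstream code treats `NA`/invalid uniformly.
Stop or ambiguous codons passed to site counting return an `NA` skip
signal, not an error. Undefined statistics that indicate a misused design
(F_G with zero operons, positional profiles with no cis loci, correlations
with fewer than two genomes) are errors, not silent `NaN`s. Modal-residue
and cognate-set ties break deterministically (alphabetical; definition
order).

## Problem sizes

The bundled tests and the acceptance script run entirely on simulated
data sized for quick, deterministic execution: 150 genomes for operon
statistics, 30 replicate pairs of 300 codons per ω level for estimator
recovery, and 6–24 genomes for end-to-end checks. These sizes give
binomial/percentile noise comfortably inside the asserted tolerances
while keeping a full run in the order of a minute.

## Known limitations

* The operon gap rule is a heuristic; organisms with unusually long
  intra-operon spacers will produce conservative (split) calls.
* Nei–Gojobori with Jukes–Cantor correction underestimates ω when
  transition bias is strong, and close pairs (very few substitutions)
  estimate ω with high variance — invalid and infinite categories make
  this visible rather than hiding it.
* Motif extraction reflects the subgroup given; a subgroup mixing distinct
  operon associations will blur tier boundaries.
* No tree inference or tree-aware statistics are provided; association
  tables can be joined to externally computed phylogenies by locus tag.
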