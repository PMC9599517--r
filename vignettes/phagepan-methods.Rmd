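---
title: "Models and methods behind phagepan"
author: "phagepan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phagepan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phagepan reconstructs, as a tested pipeline, the chain of analyses by which
complete phage genomes are recovered from environmental assemblies and then
characterized: terminal-overlap circularization, ORF calling, orthogroup
clustering and pan/core-genome accounting, average amino-acid identity (AAI),
dual-tree clade delineation, and the detection of colocated auxiliary
metabolic genes (AMGs) — in particular the Type VIII secretion system (T8SS,
Curli) gene module — with composition typing, viral-family assignment and
per-station frequency profiling. This vignette records the models, the
tunable parameters and the design decisions, in the order the pipeline runs.

## The synthetic genome population

Environmental data cannot ship with a package, so `simulate_pangenome()`
generates a genome population whose summary statistics emulate an
HTVC023P-type Pelagiphage (Podoviridae) genome set: by default 82 circular
genomes of 58,776 ± 2,523 bp at 42.1% G+C, 82 ± 9 ORFs per genome, 13 core
orthogroups, on average 17 unique genes per genome, 10 clades of at least 3
members, and a contiguous T8SS module in 9 of the 82 genomes. Every planted
feature — clade memberships, gene-to-orthogroup assignments, module
compositions and spans, terminal repeats — is returned as ground truth, so
each downstream stage can be verified exactly rather than approximately.

Key modelling choices:

* **Protein evolution** is i.i.d. substitution: each orthogroup has a random
  ancestor; each clade gets a variant at `between_clade_divergence`
  substitutions/site (default 0.30); each genome's copy adds
  `within_clade_divergence` (default 0.05). This yields ~90% within-clade and
  ~51% between-clade protein identity — clades that are separable by
  distance trees, cross-clade identity near the sub-50%-AAI regime reported
  for this kind of virus group, yet above the 30% orthogroup-clustering
  threshold so orthogroups span clades. No indels and no rate heterogeneity
  are modelled: creating separable clades does not require them, and
  substitution-only orthologs make concatenated alignments trivial.
  Ancestor and unique proteins are drawn with a realistic (UniProt-like)
  amino-acid composition rather than uniformly.
* **Genome assembly**: genes are packed head-to-tail with short intergenic
  spacers. Every gene is flanked by a fixed 12-nt "stop core"
  (`TTAATTAATTAA`, its own reverse complement) that contains a stop codon in
  all six reading frames, so no ORF can extend across a gene boundary. The
  spacers are therefore 24–50 nt rather than 0–50 nt. Codons are chosen with
  third positions calibrated (by root finding on the expected G+C of the
  weighted codon table) so the overall genome G+C lands on the configured
  value despite the A/T-only cores.
* **Spurious-ORF design-away**: a random back-translation of a ~200-aa gene
  contains on the order of six extra ORFs ≥ 90 nt in the other five reading
  frames. These are eliminated by synonymous substitution only: one codon
  (or two adjacent codons, because stop motifs in shifted frames straddle
  codon boundaries) inside the offending ORF is swapped to create an
  in-frame stop, or the ORF's start codons are destroyed. A reverse-strand
  ORF whose codons align anti-parallel to the host codons can be provably
  impossible to interrupt this way (a His host codon always spells a
  reverse-strand start; only Leu/Ser codons can spell a reverse-strand
  stop); when the protein generator can be re-drawn (unique genes) or the
  mutation re-sampled (ortholog copies) the generator retries a few times,
  and the rare survivors (well under one per genome) are recorded in the
  truth table as *incidental* overlapping ORFs. The result is a genome whose
  maximal-ORF set equals its recorded gene table exactly.
* **Genome length**: ortholog lengths are shared across genomes, so genome
  length cannot be set independently of gene content; genomes are topped up
  to a Normal(`mean_len`, `sd_len`) target with stop-cored non-coding
  filler. The mean and spread of realized lengths track the configured
  values; gene density is correspondingly slightly below that of real phage
  genomes.
* **Reproducibility**: a single master seed; per-genome and per-station
  streams are derived seeds (a fixed linear-congruential mix of master seed
  and counter), so output is byte-identical for a given configuration.
* **Partner-AMG structure**: thymidylate synthase is always planted adjacent
  to aG/PT-PPlase1 (in three clades), and ferrochelatase adjacent to a
  2OG-Fe(II) oxygenase, reproducing the colocation patterns the module
  detectors are meant to find. T8SS modules are planted contiguously, on one
  strand, in carriers clustered within a few clades; their component
  proteins take the typical sizes of their families (HK ≈ 450 aa,
  CsgF ≈ 140, CsgG ≈ 270, CsgA/B ≈ 150, FecR ≈ 310, AC ≈ 380), which puts a
  module region at roughly 6–10% of a default-size genome, matching the
  reported share of such regions.

`simulate_virome_stations()` emulates *annotated* virome contig tables (the
downstream operations all work on gene tables, not raw reads): each station
receives contigs totalling a fixed number of ORFs; a seeded fraction carry a
T8SS module drawn from a composition mixture (by default the canonical
`HK–CsgF–CsgG–CsgA/B–FecR` at 0.6, a two-HK variant at 0.3, and an extended
`…–CsgA/B–AC` variant at 0.1), assigned to a viral family; a configured
fraction of modules is cut by a contig end (and flagged in truth). Component
proteins descend from family-specific ancestors so family assignment and its
identity floors are testable. What this does *not* emulate: assembly noise,
chimeras, uneven station depths, and database contamination — tests passing
on these tables show the bookkeeping and statistics are right, not that
annotation of real viromes is easy.

## Circularization

`detect_terminal_repeat()` finds the longest prefix of a contig that recurs
as its suffix. Candidates are anchored by matching the first `min_overlap`
bases (default 100, the conventional assembler self-overlap requirement)
against the rest of the contig, then verified base by base. Defaults are
strict: identity 1.0 (the mismatch tolerance of assembler-based
circularization is not documented, so exactness is the testable contract;
`min_identity` relaxes it over an ungapped end alignment), `N` never matches
anything, and reverse-complement terminal repeats are not circularization
evidence. A repeat covering more than half the contig is degenerate and
refused. The 10-kb completeness screen (`length_filter()`) is strictly
greater-than: a 10,000-nt contig is excluded. `trim_to_circle()` removes the
tail copy, so `|genome| = |contig| − |repeat|` exactly.

## ORF calling

`find_orfs()` is a deliberately simple, deterministic caller: in every
stop-bounded stretch of each of the six reading frames it reports the
longest variant starting at an allowed initiator (`ATG`/`GTG`/`TTG`), at
least `min_len = 90` nt including the stop. On circular genomes the scan
runs on the doubled sequence and deduplicates wrap copies, making calls
rotation invariant. `GTG`/`TTG` initiators are translated literally (the
generator only plants `ATG` starts, so truth comparisons are unaffected).
This caller is *not* a trained gene finder — no coding-potential or RBS
scoring — which is exactly why the generator designs its genomes so that
the maximal-ORF set is the planted gene set. Externally called genes can be
imported from GFF3 and take precedence.

## Orthology, AAI and screening

`protein_similarity()` is global (Needleman–Wunsch) alignment with affine
gaps under BLOSUM62 (`gap_open = 10`, `gap_extend = 0.5`); identity is
counted over all alignment columns with gaps in the denominator — a
conservative reading of "amino-acid similarity", stated explicitly because
the term is often left undefined. `build_orthogroups()` takes the connected
components of the edge graph thresholded at 30% identity and 0.5 coverage
(of the shorter protein). This replaces score-based MCL clustering of the
standard orthology tools with something deterministic and oracle-testable;
it is adequate at the divergence regimes the generator plants, but counts
from real data produced by those tools (e.g., a 623-orthogroup inventory)
are reproducible only with the tools themselves. Orthogroup ids are assigned
from the lexicographically smallest member, so output order is
deterministic.

The k-mer Jaccard prefilter (`candidate_pairs()`) keeps all-vs-all runs
tractable. Its defaults (`k = 5`, `jaccard_min = 0.05`) are safe above
roughly 60% identity; near the 45–50% identity regime of cross-clade
orthologs the 5-mer survival probability (~identity^5) is too small, so the
pipeline-scale runs use `k = 4`, `jaccard_min = 0.01`. A missed cross-clade
edge is tolerable there because orthogroups are components: any spanning
path keeps the group connected.

`compute_aai()` is the mean identity over reciprocal best hits between two
proteomes, ties broken by score then gene id. Because global alignment
produces a "best hit" even between non-homologs (where a search program
would simply find nothing), RBH pairs below a 20% identity evidence floor
are discarded; without this the AAI of two genuinely related proteomes is
dragged down by their unique-gene pairs. `AAI(g, g) = 100` and symmetry hold
by construction. `screen_by_reference()` retains genomes with at least one
protein at ≥ 45% global identity to a reference set — the marker screen
(DNA polymerase A against cultured isolates) that defines membership of the
lineage; whether the published screen meant global or local identity is not
documented, so the choice is explicit here.

## Trees and the dual-tree clade rule

The clade *rule* — not the tree engine — is the bespoke computation, so
maximum-likelihood reconstruction is out of scope: trees from external ML
tools are consumed as newick (`read_support_tree()`, which rescales
fractional supports to percent), and a built-in neighbor-joining path
(`nj_tree()` over p-distances, classical Felsenstein column-resampling
bootstrap in `bootstrap_supports()`) exists so the rule is testable end to
end on synthetic alignments.

`delineate_clades()` implements: a clade is reported when the same leaf set
appears as a supported bipartition in **both** trees, with ≥ 3 members and
≥ 90% bootstrap support in each. Candidates are the minority side of each
internal edge (making the rule independent of rooting); only maximal
candidates are reported, so nested supported sub-clades are absorbed and the
output is pairwise disjoint. Two partially overlapping surviving candidates
— impossible within one tree, possible across two — cause both to be
dropped with a warning rather than an arbitrary choice. `sister_group_labels()`
answers the interrogation step ("what is this clade's nearest neighbor?"),
reporting the sister group's taxonomy labels and whether the query is
monophyletic.

## AMG and module analysis

All module operations work on annotated gene tables (one row per gene with
`label`, `category`, `component`). Gap and window parameters uniformly count
*intervening genes*: `max_gap_genes = 1` tolerates one unannotated gene
inside a module run or between a partner pair — close to the contiguous
operons in the source figures while robust to annotation dropouts
(`max_gap_genes = 0` restores strict contiguity).

* `classify_amgs()`: genes with a cellular-function category, minus the
  curated core-viral set.
* `adjacency_implication()`: does every genome encoding X have a Y within
  the gap of some X copy? (The observed rule: wherever ferrochelatase, an
  adjacent 2OG-Fe(II) oxygenase.) Counterexamples are listed.
* `partner_amg_pairs()`: AMG pairs that are both colocated (window default
  5 intervening genes) and functionally related (same AMG category).
* `extract_modules()`: maximal runs of T8SS components; the composition
  string is read in canonical orientation — the orientation in which CsgF
  precedes CsgG, falling back to the majority strand — so forward- and
  reverse-strand modules type identically. Duplicate components (two HKs, a
  second CsgA/B) are preserved. `filter_terminal()` removes instances whose
  contig starts or ends in a component — possible truncations of an
  incompletely assembled region.
* `assign_family()`: nearest labelled reference decides the family, unless
  its identity falls below that (component, family) floor — the minimum
  identity observed among the known-affiliation references themselves
  (`family_identity_floors()`) — in which case the protein stays
  unassigned. Zero-count conventions in `pairwise_count_ratio()` (skip
  pairs where both counts are zero; a single zero scores 0) are this
  package's choice; the min/max-per-unordered-pair reading of "pairwise
  average ratio" is likewise documented rather than assumed.

## Problem sizes and numerical choices

The test suite runs on deliberately scaled-down simulations (6–70 genomes of
4–20 kb, 200–500 bootstrap replicates, 65 stations at 1,600–4,000 ORFs
each); the acceptance script runs the full study-scale configuration (82
genomes of ~59 kb, 65 stations, 500 bootstrap replicates on a marker-gene
tree and a five-gene concatenation tree, mirroring the single-marker vs
multigene design). Statistical checks against planted rates use 3-sigma
binomial/multinomial bands; exact checks (ORF sets, orthogroup partitions,
module compositions, terminal-filter membership) use equality. Alignment
scoring ties are resolved deterministically (score, then lexicographic id);
NJ ties follow the underlying implementation; bootstrap seeds are explicit
arguments.

## Known limitations

* The ORF caller reports maximal ORFs only; overlapping genes in other
  frames, common in real phages, are not modelled (and are designed away in
  the synthetic genomes).
* Connected-component orthology can chain distinct families through
  intermediate sequences in dense real datasets; the planted regimes avoid
  this, real data may not.
* The NJ + p-distance tree path is a stand-in for ML reconstruction; it is
  consistent on the planted (additive-in-expectation) divergences but not a
  substitute for model-based inference on real alignments.
* Relaxed-identity terminal repeats are found via a seed anchored at the
  contig start; a repeat whose first 100 bases are heavily mismatched could
  be missed in relaxed mode.
* Station tables are annotation-level; nothing about read mapping,
  coverage, or assembly quality is simulated.
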