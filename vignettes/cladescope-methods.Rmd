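---
title: "CladeScope: methods and design"
author: "CladeScope authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CladeScope: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CladeScope)
```

# Scope

CladeScope implements the comparative-genomics machinery used to
characterise a bacterial clade at the genus-to-family scale: pan- and
core-genome construction with rarefaction curves, fragment-based average
and total nucleotide identity (ANI/TNI) with per-taxonomic-rank
distributions, tree-based phylogroup delimitation under a monophyly
constraint, node-depth analysis of metabolic traits, and a set of feature
screens (cell-envelope proteases, plasmid-derived contigs, CAZyme hit
reconciliation, glycolysis gene presence, partial genes at contig
boundaries, and niche association). Because the real inputs for such a
study are hundreds of draft assemblies and all-vs-all sequence searches
that take hours, the package ships a genome-evolution simulator that
generates desk-scale clades with complete ground truth, so that every
stage is verifiable end to end.

# The simulator

`simulateClade()` draws a birth--death tree (`ape::rphylo`; a fixed tree
can be supplied instead), places `core_size` gene families at the root,
and evolves everything toward the tips:

* **Gene content.** Core families are never lost by construction -- the
  core genome is the quantity the downstream analysis must recover, so its
  truth must be unambiguous. Accessory families are gained at most once
  (no convergent gain, keeping the truth matrix unambiguous): per branch,
  each not-yet-gained family receives a Poisson number of gain events with
  mean `gain_rate x branch length`, and the first event in preorder fixes
  the gain point. Families present at a node are lost below it when a
  Poisson draw with mean `loss_rate x branch length` is positive. The raw
  event counts per branch are recorded in the truth set so the Poisson
  behaviour itself is testable. Families whose lineage dies out again are
  dropped from the truth matrix: truth covers realised families only.
* **Sequence evolution.** Sites evolve under the Jukes--Cantor kernel:
  a site changes with probability `3/4 (1 - exp(-4/3 d))` and moves to a
  uniform alternative, which composes exactly along branches. In coding
  sequence, a substitution that would create an in-frame stop codon is
  redrawn among the remaining alternatives; this preserves the per-site
  substitution probability (so identity calibrations against the
  closed-form expectation remain valid) while keeping genes translatable.
  Genes are `ATG` plus sense codons; proteins are direct translations
  (the bacterial genetic code has the standard amino-acid mapping).
* **Geometry.** Default gene length is 900 nt (sd 150), matching typical
  bacterial genes; this matters because the clustering thresholds are
  *relative* (25% identity over 40% of the gene length), and with very
  short proteins chance local alignments can reach 40% coverage, which
  real proteins essentially never do under BLOSUM62. Intergenic spacers
  (30 nt) evolve without the stop constraint.
* **Fragmentation.** Tip genomes are cut into `n_contigs` contigs at
  intergenic positions, so genes stay intact; the generic
  `fragmentAssembly()` operation cuts uniformly anywhere and is used when
  gene integrity is not required. Planted features (CEP architectures,
  plasmid-derived contigs, CAZyme hit sets) are appended with their
  expected classifications recorded.

All randomness flows from one seed in a documented order (tree, root
sequences, then branches in preorder); equal configurations give
byte-identical output.

What the simulator does *not* emulate: assembly and sequencing error,
rearrangements, codon-usage and amino-acid composition realism,
horizontal transfer with convergent gains, and rate heterogeneity across
sites. Green tests on simulated clades therefore demonstrate the
correctness of the machinery under the stated model, not robustness to
artefacts of real draft assemblies.

# Alignment layer

All similarity decisions go through Smith--Waterman local alignment with
affine gaps (Biostrings engine; BLOSUM62, gap 11/1 for proteins; +1/-1,
gap 5/2 for nucleotides, both strands tried). E-values are deliberately
not computed: they depend on database size, and the clustering stages of
the method are defined purely by identity and coverage thresholds.
Identity is matches over alignment columns; coverage is the aligned span
over the sequence length; thresholds are inclusive. A gap of length L
costs `open + L x extend`, so a linear-gap scheme is `open = 0`.

The all-vs-all kernels seed candidate pairs with shared words
(`word_size = 5`, at least 2 shared words by default), exactly as
BLAST-style search engines do; `min_shared_kmers = 0` disables the filter
and aligns every pair. The default keeps >99% sensitivity for homologs
above roughly 50% identity while skipping the vast majority of unrelated
pairs; analyses targeting the 25--40% identity twilight zone should lower
the filter. The traceback tie-break among co-optimal alignments is the
engine's deterministic one.

# Pan-genome construction

Two complementary routes are provided.

**Greedy accumulation** (`accumulatePanFamilies()`): genomes enter in a
fixed-first, seed-shuffled order; each incoming gene joins the
earliest-founded family whose *representative* (founder gene) it hits at
25%/40%, else founds a new family. Comparing against representatives
rather than all members keeps the procedure order-stable and linear in
the number of families; within-genome paralogs above threshold collapse
into one family, since family counts, not gene counts, are the quantity
of interest. Pan (families seen) and core (families shared) rarefaction
curves are computed from the resulting presence matrix over seeded
permutations of the genome order (10 by default, mean and sd reported) --
the standard rarefaction practice, which keeps 100-permutation
monotonicity checks cheap.

**RBH + two-stage clustering** (`buildGeneFamilies()`): reciprocal best
hits at 25%/40% per genome pair (ties broken by identity then
lexicographic id), then Markov clustering (expansion 2, inflation 2.0,
convergence when the matrix change drops below 1e-6, at most 100
iterations -- documented defaults, configurable) on the identity-weighted
graph, followed by single-linkage merging of clusters sharing any RBH
edge. The single-linkage stage can re-join clusters that Markov
clustering split across a weak bridge, up to whole connected components;
both stages are exposed so either behaviour can be examined. Orthology is
RBH-only: no quartet-based paralog filtering is applied, which may split
or merge families at the margin relative to quartet-aware pipelines.
Core families are those with at least one member in every genome;
`taxonDropoutCore()` re-runs the whole construction on a reduced taxon
set, and `fragmentationSensitivity()` recomputes curves after excluding
genomes above each contig-count level and reports the Spearman
correlation between per-genome marker-family counts and contig counts
(zero-variance vectors yield rho = 0 by the documented ties policy).

# ANI and TNI

`ani()` chops the query genome into consecutive 1020-nt fragments
(trailing fragments under 100 nt are discarded as unstable), aligns each
against the whole subject on both strands, keeps fragments with at least
30% identity over at least 70% of their length, and averages the kept
fragment identities; the reported value is the mean of the two
directions. These parameter values follow the classic fragment-ANI
protocol and are all configurable. A pair with no passing fragment is
undefined (`NA`), never 0.

`tni()` is `2M / (L_a + L_b)` with `M` the identically aligned
nucleotides summed over kept fragments (averaged over the two directions,
making the value symmetric). The exact published formula for this
statistic is not restated in the motivating work; the symmetric form
above is this package's documented interpretation, chosen because it is
bounded by the alignable fraction (`TNI <= 2 min(L)/ (L_a+L_b)`) and
reduces to `ANI/100` for indel-free full-coverage pairs up to the few
matches clipped at fragment boundaries (tolerance about 0.005). Local
alignment clips terminal mismatches of a fragment, so single-fragment
identities sit slightly above the raw mismatch fraction; across
replicates the mean agrees with direct mismatch counting to well under
0.5 percentage points at 1--10% divergence (the acceptance suite measures
exactly this).

`rankDistributions()` assigns each genome pair to the lowest taxonomic
rank shared by the two taxa (pairs sharing no listed rank pool into the
most distant bucket, `class`) and histograms the pair values on shared
bin edges -- 100 bins over the observed global range, so intersection
areas between rank curves are well defined. Kernel density estimation is
deliberately avoided: fixed binning keeps the overlap statistic exact and
parameter-free.

# Phylogroups

Distances are patristic by default (`1 - TNI` or node-depth variants can
be supplied); the within-group and between-group pair distances are
histogrammed on shared edges and compared by the intersection area
`sum(min(f_w, f_b)) x binwidth`, which is 1 for identical and 0 for
disjoint distributions. `optimizePhylogroups()` replaces a manual
editing procedure with a deterministic greedy local search: moves are
single-taxon reassignments, group merges, and splits of a group into the
child clades of its most recent common ancestor; a move is admissible
only if every resulting group is monophyletic and the objective stays
defined (at least one within- and one between-pair -- all-singleton
groupings are rejected rather than scored 0), and the first admissible
strictly improving move in a documented scan order is accepted. The
objective is therefore monotone non-increasing, the procedure idempotent,
and on small trees its optimum matches exhaustive search over all
monophyletic groupings (the acceptance suite enumerates them). Node
depth (`nodesToRoot()`) counts the internal nodes from a leaf to the
root, excluding the leaf and including the root -- equivalently the edge
count -- so a leaf hanging off the root has depth 1; the published
counting convention is not stated, so this one is fixed and used
consistently, including in `traitMeanDepth()` for the
homofermentative/heterofermentative comparison.

# Feature screens

* **Contig spacers and partial genes.** Contigs are joined by the 36-nt
  spacer `NNNNNCACACACTTAATTAATTAAGTGTGTGNNNNN`, which carries stop
  codons in all six frames and is its own reverse complement; the offset
  map makes insertion exactly invertible. A gene truncated at a contig
  boundary carries the spacer prefix `NNNNNCACACACTTAA` at its 3' end (or
  the reverse complement at its 5' end, both checked on the coding
  strand), giving the four partial statuses.
* **Cell-envelope proteases.** A candidate needs a subtilase-domain span
  and the catalytic triad in the order Asp, His, Ser inside it. Triad
  positions come from a packaged profile of three short motif windows
  around the catalytic residues; the anchor class follows the precedence
  truncated (artificial 3' end) > canonical `LPxTG` in the 60-aa
  C-terminal window > derivative motif > SLAP domain > none. The
  derivative pattern `[LIVFM]-P-x-[TSA]-[GSNDA]` (canonical matches
  excluded) is this package's documented, configurable guess -- no
  published definition exists. Candidate lengths outside a configurable
  plausible range (default 800--2600 aa, bracketing the observed
  1097--2270 aa with margin) are rejected.
* **Plasmid contigs.** A contig group is assigned to a plasmid iff at
  least 25% of the summed contig length aligns, at least 25% of the
  plasmid is covered, and the alignment-length-weighted mean identity is
  at least 70% -- all inclusive; the identity threshold is applied to the
  aggregate (weighted mean) since the published wording is ambiguous
  between per-alignment and aggregate readings.
* **CAZymes.** Gene-family calls supported by both the HMM scan (e-value
  < 1e-5) and the similarity search (identity >= 40%, coverage >= 50%,
  e-value < 1e-5) are retained; single-source calls survive only with a
  profile-database confirmation; conflicting families on a common gene
  are both kept and flagged. Output is a genome x family copy-number
  matrix.
* **Glycolysis.** Presence is annotation evidence OR a confirmed
  homology hit; phosphoglycerate mutase is present iff any query hit has
  bit score strictly greater than 100.
* **Niche association.** Per-feature Kruskal--Wallis with tie correction
  and the chi-squared approximation (the base-R default); niche groups
  under a configurable minimum size (default 3) are excluded with a
  warning, and constant features return H = 0 rather than an
  indeterminate statistic.

# Numerical choices and degenerate inputs

Histogram ranges of width zero are widened to one unit around the value;
undefined ANI is `NA` while undefined TNI is 0 (no matched nucleotides);
Spearman correlations of zero-variance vectors are 0 with p = 1;
`intersectionArea()` returns `NA` when either side is empty. Every
stochastic routine takes a seed and restores the caller's RNG state.

# Problem sizes

The shipped tests and the acceptance script run on clades of 8--10
genomes with 200 core families of ~900-nt genes, identity calibrations on
2--3-kb genomes with 510-nt fragments, and exhaustive phylogroup
enumeration on 8-leaf trees -- sizes chosen so the full suite executes in
a few minutes while still being large enough that recovery statistics
(e.g. a 200-family core recovered exactly, 30/30 planted protease
architectures) are meaningful.

# Known limitations

Greedy pan families depend on the accumulation order by construction
(the published procedure shares this property); RBH-only orthology can
differ from quartet-aware orthology at the margin; the phylogroup
optimiser is a local search and is validated against exhaustive
enumeration only at small leaf counts; the simulator's sequence model is
deliberately minimal (Jukes--Cantor, no indels), so identity calibration
tests say nothing about gapped-alignment behaviour at high divergence;
and chance local alignments between short (< ~150 aa) unrelated proteins
can pass the permissive 25%/40% thresholds, which is inherent to the
thresholds rather than to this implementation -- the e-value cutoff that
suppresses such hits in database searches is intentionally out of scope.
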