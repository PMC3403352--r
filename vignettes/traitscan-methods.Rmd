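---
title: "Methods: trait-linked family scanning and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-linked family scanning and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical and design choices made where
the procedure was genuinely open.

## The inference chain

The package operationalizes a classical comparative-genomics argument: if a
gene family is functionally coupled to a trait — here, Holliday-junction
resolution by the bacterial RuvABC resolvasome or its RuvAB/RecU variant —
its phyletic profile should track the trait across genomes, its gene should
recur in the chromosomal neighborhood of the trait's genes, and its
protein tree may split into subtypes with distinct conserved residues. The
chain is: homology search → orthology → profiles → trait calls →
co-occurrence + neighborhood → linkage ranking → alignment → tree →
subtypes → specificity-determining positions (SDPs).

## Homology and orthology

Members are detected by exact Smith–Waterman local alignment under BLOSUM62
with affine gaps (open 11, extend 1, the common BLAST convention; a gap of
length $k$ costs $11 + k$). Significance uses the Karlin–Altschul form
$E = K\,m\,n\,e^{-\lambda S}$ with the published ungapped BLOSUM62
constants $\lambda = 0.318$, $K = 0.134$; candidates are kept at
$E \le 0.1$, a deliberately permissive threshold whose false positives are
controlled downstream. Orthology is by reciprocal best hit against the
seed set, with a "seed-set vote" standing in for domain-database
corroboration: a gene is considered for family $f$ only if its overall best
seed belongs to $f$. Ties on raw score break by E-value, then lexicographic
ID; one ortholog per family per genome, extra members reported as paralogs
(in real bacterial data most genomes carry a single copy of a family like
YebC, so the single-ortholog model is the informative one). Full dynamic
programming is affordable at this scale; no heuristic seeding is used, and
the search operates on annotated proteomes — unannotated ORFs are out of
scope.

## Profiles, trait signature, and linkage scores

The phyletic profile is the binary genomes × families matrix of ortholog
presence, each call carrying its supporting gene ID. The trait is called
per genome from four markers: `RuvABC` when RuvA, RuvB, RuvC are present
without RecU; `RuvAB+RecU` when RecU replaces RuvC; `both` when all four
co-occur; `RuvAB-only` when neither resolvase is present; otherwise
`absent`. RuvC without both RuvA and RuvB is biologically anomalous and is
flagged rather than silently accepted.

Because no calibrated database score is available offline, the linkage
score is the package's own definition, kept deliberately simple and
documented here rather than hidden in configuration:

* **Co-occurrence** $s_{\mathrm{cooc}} = 1 - p$, where $p$ is the
  one-tailed Fisher exact enrichment p-value of the candidate's profile
  against the trait profile (Jaccard and mutual information are reported
  alongside as descriptive statistics).
* **Neighborhood** $s_{\mathrm{nbr}} = \min(0.999, \sum_g w_g / n)$,
  where genome $g$ contributes $w_g = 1$ if candidate and anchor share an
  operon, $0.5$ if their gene-rank distance is at most $D = 3$, else $0$.
  Operons are maximal same-strand runs with intergenic gaps
  $\le 100$ bp — a standard operon-prediction heuristic; both thresholds
  are configurable because "same operon" and "very close" are conventions,
  not measurements.
* **Fusion** a binary bonus $s_{\mathrm{fus}} = 0.5$ when one gene aligns
  to seeds of the candidate family and of an anchor family over
  $\ge 60\%$ of each seed on disjoint spans of the gene.

Channels combine as the complement of independent failure,
$1 - (1 - s_{\mathrm{cooc}})(1 - s_{\mathrm{nbr}})(1 - s_{\mathrm{fus}})$,
and candidates are ranked by the combined score. Profiles are treated as
i.i.d. across genomes; phylogeny-aware co-occurrence corrections are a
known, deliberate omission — shared ancestry can make an unrelated family
look correlated with the trait, which is why the neighborhood channel
carries real weight in the combination.

## Alignment, distances, trees, subtypes

The aligner is a standard guide-tree progressive method: 3-mer distances,
a UPGMA guide tree, and profile–profile Needleman–Wunsch merges under the
same BLOSUM62/affine costs, with end gaps penalized like internal ones and
deterministic tie-breaking (diagonal over up over left). Columns with more
than 50% gaps are masked before distance estimation, keeping an index map
so downstream column reports can be stated in original alignment
coordinates.

Distances use the closed-form Kimura protein correction
$d = -\ln(1 - p - 0.2p^2)$ of the mismatch fraction $p$ over mutually
ungapped columns. The correction is undefined for $p \gtrsim 0.8541$;
such pairs are set to a ceiling of 10 expected replacements per site with a
warning — a pragmatic choice that keeps saturated pairs finite without
letting them dominate. The closed form was preferred over ML distances
under an empirical rate matrix for exact testability.

Trees are canonical Saitou–Nei neighbor joining, which is provably exact on
additive matrices (a property the test suite exercises against random
trees). Ties in the $Q$ criterion break by the smallest row-index pair;
negative branch lengths are clamped to zero with the deficit moved to the
sister branch so the pair's path length is preserved. Bootstrap support
counts, over column resamples, how often each internal bipartition of the
original tree recurs. Fitch parsimony scoring (gaps treated as missing) is
provided for evaluating alternative topologies; parsimony tree *search* is
intentionally absent because the trees of record are NJ trees.

Subtypes are read off the midpoint-rooted tree: its two root clades are the
subtypes, with subtype I the clade containing a user-designated reference
leaf, defaulting to the larger clade. Midpoint rooting is a choice — the
subtype boundary could equally be drawn by an outgroup, which is supported
via `rooting = "<leaf>"` — but for an anciently duplicated family whose
subtypes are separated by a long internal branch it is the natural one.

## Specificity-determining positions

Within each subtype, each column's consensus residue and conservation
fraction are computed with gaps counting against conservation (a gap can
never be the conserved state). With strictness $s$ (default 1.0, i.e.
"strictly conserved"; 0.9 recommended for noisy data), a column is
I-specific when its subtype-I consensus reaches conservation $\ge s$ in I
and frequency $\le 1 - s$ in II; II-specific symmetrically; a column
specific on both sides — fixed for different residues — is flagged
`diagnostic`, the biologically interesting case; columns conserved on the
same residue in both subtypes are `shared-conserved`. Lowering $s$ can only
grow the specific sets (a monotonicity the tests check).

## The synthetic-data generator

The generator's defaults are the package's study conditions; they are fixed
once and the validation suite runs against them.

* **Species tree**: Yule (pure birth) with $n$ leaves, rescaled to height 1.
* **Gene content**: each family's presence evolves as a two-state Markov
  chain (gain 1, loss 0.5 per unit height; stationary presence 2/3); at
  long times leaf presence converges to birth/(birth+loss), which the tests
  verify. RuvA and RuvB are universal, as in real bacteria; a trait chain
  (root present) decides which genomes carry a resolvase and a slow binary
  lineage character decides whether it is RuvC or RecU, emulating the
  firmicute replacement. Twenty decoy families evolve independently.
* **Planted partner**: present iff the trait is present, with probability
  0.95 (`linkage_strength`), and placed immediately downstream of the
  resolvase gene — same strand, gap uniform on [0, 100] bp — in 60% of
  co-occurring genomes; otherwise it lands at a random position. Background
  intergenic gaps are drawn from [200, 500] bp so chance adjacency does not
  mimic an operon.
* **Two-subtype family**: the partner's sequences come from an ancient-
  duplication model: the leaves split into two clades, each evolving down
  its own Yule-shaped gene tree from a *common* ancestral sequence with
  root-to-leaf substitution probability `subtype_divergence / 2` per
  lineage. All fixed between-clade differences are the planted diagnostic
  columns (default 20 of 200 residues, the order of magnitude a
  subtype-annotated alignment figure of a ~200-residue family highlights),
  held under divergent selection: residue $a$ in clade I, $b \ne a$ in
  clade II, never mutating. Background columns therefore drift within
  clades but share their ancestral state across clades — the regime in
  which strict SDP calling is informative. Other families' per-genome
  copies differ from their seed at 5% of sites.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: horizontal transfer, genome rearrangement and
inversions, rate heterogeneity across sites or lineages, annotation errors
and missing gene calls, paralog proliferation, database-scale taxon
sampling, and nucleotide-level search semantics. Recovery rates on this
generator are upper bounds for field performance.

One behavior of the model worth knowing when reading SDP output: within a
clade, a substitution on a branch near the clade root can sweep to near
fixation, producing an *evolved* near-diagnostic column. At strictness
below 1.0 the classifier flags such columns — correctly, in the sense that
they do discriminate the subtypes — but they are not in the planted truth
set, so precision measured against planted columns alone understates the
classifier and should be read with that in mind (at strictness 1.0 the
planted set and the detected set coincide on noise-free data).

## Determinism and problem sizes

All randomness flows from one root seed through named per-stage substreams,
so a full pipeline rerun with the same configuration is byte-identical —
the run report records MD5 checksums of every artifact to make this
checkable. The validation suite uses 50-genome simulations with 20 decoys
for linkage recovery, 30-leaf families for subtype and SDP recovery (20
replicate seeds each), 200 random additive matrices of 4–8 taxa for NJ
exactness, exhaustive enumeration for the alignment oracle (3-letter
alphabet, lengths to 5), all 2×2 tables with total at most 30 for the
Fisher oracle, and all unrooted topologies with 4–5 leaves and 4 states
for the parsimony oracle — sizes chosen so each property is checked
densely while the whole suite stays comfortably interactive.

## Known limitations

Co-occurrence ignores phylogenetic non-independence; the E-value model uses
ungapped constants for gapped scores (adequate for ranking, not for
absolute significance); the single-ortholog-per-genome rule can hide
lineage-specific duplications from the profile (they remain visible as
paralogs); midpoint rooting can misplace the subtype boundary when the
between-subtype branch is not the tree's longest path; and operon calls
from intergenic distance alone miss transcription-unit structure.
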