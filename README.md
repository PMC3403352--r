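# traitscan

Comparative-genomics scanning for gene families functionally linked to a
genomic trait, built around the inference chain classically used to tie the
YebC family to the bacterial Holliday-junction resolvasome: homology search
with E-value filtering, bidirectional-best-hit (BBH) orthology, phyletic
profiling with a trait signature, gene-neighborhood and operon analysis,
combined linkage ranking, and protein phylogeny with subtype partitioning
and detection of subtype-diagnostic residues.

## Who this is for

Microbial comparative genomicists who want a self-contained, testable
version of the "guilt by association" toolbox: given annotated proteomes
(FASTA + GFF3), a set of seed proteins defining marker families (here RuvA,
RuvB, RuvC, RecU), and optionally a reference species tree, the package

1. finds family members by Smith–Waterman local alignment with
   Karlin–Altschul E-values (cutoff `E ≤ 0.1`), assigning one ortholog per
   family per genome by reciprocal best hit;
2. builds the genomes × families presence/absence (phyletic) profile and
   calls the Holliday-junction resolution trait per genome from the
   signature *RuvABC present, or RuvAB together with RecU*;
3. scores every other family against the trait by co-occurrence
   (Jaccard, mutual information, one-tailed Fisher exact `p`) and by
   chromosomal neighborhood (operons inferred from same-strand runs with
   intergenic gaps ≤ 100 bp; gene-rank distance windows), combining the
   channels as `1 − (1 − s_cooc)(1 − s_nbr)(1 − s_fus)`;
4. aligns the members of a candidate family (progressive profile aligner),
   computes Kimura-corrected distances `d = −ln(1 − p − 0.2p²)`, builds a
   neighbor-joining tree with bootstrap support, splits it into two
   subtypes at the midpoint root, and reports alignment columns strictly
   conserved within one subtype but absent from the other
   (specificity-determining positions).

A synthetic-genome simulator plants all of this structure (gene gain/loss
on a Yule species tree, a partner family tracking the trait, operon
placement, a two-subtype protein family with diagnostic columns) so every
stage can be validated against known truth.

## Worked example

```r
library(traitscan)

cfg <- sim_config(n_genomes = 12, n_decoy_families = 5, seed = 7)
simulate_dataset(cfg, "simdat")

rc <- run_config(genome_dir = "simdat/genomes",
                 seeds_fasta = "simdat/seeds.faa",
                 seed_families_tsv = "simdat/seed_families.tsv",
                 out_dir = "run1", seed = 7, bootstrap_replicates = 20)
run_full(rc)

head(read.delim("run1/linkage_report.tsv"), 3)
```

```
  family_id jaccard mutual_information    fisher_p    s_cooc     s_nbr fusion  combined rank
1      yebC     1.0        0.636514168 0.002020202 0.9979798 0.4583333  FALSE 0.9989057    1
2   decoy05     0.8        0.219512149 0.090909091 0.9090909 0.1666667  FALSE 0.9242424    2
3   decoy02     0.5        0.007102047 0.575757576 0.4242424 0.1666667  FALSE 0.5202020    3
```

The planted partner (`yebC`) ranks first: its presence matches the trait in
every genome (`jaccard = 1`, Fisher `p ≈ 0.002`, so `s_cooc ≈ 0.998`) and
its gene sits in the resolvase operon in about half of the co-occurring
genomes (`s_nbr ≈ 0.46`). `run1/subtype_labels.tsv` then carries the two
subtypes of the partner family read off the midpoint-rooted NJ tree, and
`run1/sdp.tsv` the columns diagnostic between them.

The same flow is scriptable from a shell via `inst/scripts/traitscan`
(subcommands `simulate | run | profile | link | tree | sdp | report`).

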