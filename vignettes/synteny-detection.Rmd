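---
title: "Exon-level synteny detection: model, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-level synteny detection: model, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenr)
```

# The model

`syntenr` detects conserved regions between two annotated genomes by
comparing **translated exons** rather than nucleotides or whole genes.
Working on amino-acid sequence makes the comparison insensitive to
codon-usage divergence; working on exons rather than genes tolerates exon
gain, loss and shuffling within otherwise conserved loci; and ignoring the
order of matches within a cluster tolerates the inversions and local
rearrangements that accumulate quickly in fast-evolving microorganisms.

The pipeline's objects are:

* a **hit** `h = (r_β, r_γ)`: a reciprocal (bi-directional) protein match
  between one exon of organism β and one of organism γ, reduced to a genomic
  interval on each organism, with e-value `E(h)` and quality
  `K(h) = (1 − min(1, E)) · (‖r_β‖ + ‖r_γ‖)/(‖x_β‖ + ‖x_γ‖)`;
* a **dendrogram** per scaffold pair: single-linkage clustering of that
  pair's hits under `d(h_i, h_j) = dist(r_iβ, r_jβ) + dist(r_iγ, r_jγ)`,
  with `dist` the bp gap between intervals;
* a **candidate cluster** at every node, scored by
  `s(C) = 2 Σ_{h∈C} K(h) − Σ_{e∈U_C} max_{h∈H_e} K(h)` with
  conservation ratio `τ_C = (n_C + 1)/(n_Cβ + n_Cγ + 1)`, where `U_C` are
  the unaccounted exons inside the cluster's spans and `n_Cχ` counts those
  that hit *somewhere* in the genome.

Two asymmetries in the score are intentional and carry the model's
assumptions. A gap exon that matches nothing on the other genome is ignored
(insertions and orphans should not destroy a cluster), whereas a gap exon
whose best match lies elsewhere argues *against* the cluster and is charged
at that best quality. And exon order contributes to the clustering (nearby
hits merge first) but not to the score — the method is built for settings
where gene shuffling is common, so order conservation is evidence it
deliberately does not demand.

# Statistical testing

The null hypothesis for a cluster of given shape `(n_C, n_Cβ, n_Cγ)` is that
its member qualities are an arbitrary draw from the genome-wide pools: the
permuted score is
`s_p = 2 Σ_{k≤n_C} P_k − Σ_{k≤n_Cβ} P*_kβ − Σ_{k≤n_Cγ} P*_kγ`,
with each sum drawn without replacement from a shuffled copy of its pool
(`P`: all hit qualities; `P*_χ`: the best quality per exon of organism χ).
Permuting scores after clustering — rather than re-clustering randomly
placed hits — is what makes the test computationally feasible.

Three devices keep the permutation budget tractable:

* **Two-gene rule.** Nodes touching fewer than two genes on either organism
  are homology, not synteny; they are never tested. Requiring two genes on
  *each* side (not just one) is this package's reading of "at least two
  genes": a region of one gene matched by two genes elsewhere is still a
  one-gene statement on one side.
* **Early stopping.** Drawing stops once `k = 10` permuted scores have
  reached the observed one. The budget at correction factor `m` is
  `⌈10 m / α⌉` draws, which makes the stop conclusive: a stopped test has
  `p ≥ (k+1)/(draws+1) > α/m` no matter how the remaining draws would have
  fallen, so early stopping can never flip a decision (this is asserted
  empirically in the test suite, and holds by construction).
* **Normal approximation.** For clusters with `n_C ≥ clt_min_n` (default
  30) the null is approximated by a normal whose mean and variance follow
  from the exact pool moments with a finite-population correction
  `(N−n)/(N−1)` per pool, the three pools treated as independent. The
  default threshold of 30 is validated by cross-checking the approximation
  against `10^5` permutations over a ±4 SD score grid (agreement within
  0.01); below it the permutation path is used. For degenerate pools
  (`n = N`, or zero variance) the approximation collapses to the correct
  point mass.

## The dynamic cut and its correction

Testing every node would require a Bonferroni factor of `2|H|` (every hit
contributes at most two nodes). Instead the correction factor **is the
number of nodes actually tested**, grown during the traversal: it starts at
1 with the first test and increases by one for each child the traversal
descends into (including children tested only to compare against their
parent). A node is cut — reported, ending its branch — when it passes the
two-gene rule, has `τ_C ≥ τ`, is significant at the *current* level
(`p·m ≤ α`), and no child offers a strictly lower p-value while satisfying
`τ`. Ties between parent and child go to the parent: the larger syntenic
context is preferred and the rule is deterministic.

Because `m` grows after a node was called significant, previously accepted
nodes are re-examined at the final factor, reusing their earlier permutation
draws (each test owns a seeded RNG substream whose state is saved, so
extending a test never repeats or wastes draws). The whole procedure
iterates until the cut set and the factor stop changing; it terminates
because `m` is bounded by `2|H|` and draws per node by the budget. One
global factor is shared across all scaffold-pair trees — the `2|H|` bound is
global, so the α budget is too. When parent and child are compared on
permutation p-values, both records are first extended to the same draw
count; otherwise the child, tested later at a higher `m` and hence a larger
budget, could win the comparison on resolution alone.

# Synthetic study conditions

The generator (`synth_spec()` / `synth_generate()`) builds random gene
models — by default 2 scaffolds per organism, 20 genes per scaffold, 2–4
exons per gene of 90–300 bp, introns of 60–180 bp, intergenic gaps of
200–800 bp — and injects hits directly:

* **planted blocks**: positionally paired genes with reciprocal
  full-coverage hits at a chosen e-value (default 0, so `K = 1`); exon
  lengths are multiples of 3 with frame 0 so that the full peptide maps back
  onto exactly the full exon and the planted quality is achieved without
  rounding;
* **duplications**: one β gene hit by several γ copies (tandem or on
  another scaffold), which is how both shared-endpoint region views and
  exons claimed by several clusters arise;
* **noise**: uniformly random exon pairs with qualities drawn from
  Beta(1, 5) — mostly weak matches with an occasional strong one, a
  plausible shape for the tail of spurious alignments (`E = 1 − K`, so the
  requested quality is exact).

Planted exon pairs also share their coding sequence, so a real protein
aligner reproduces the planted hits from the FASTA/GFF3 files; the test
suite exercises this with BLASTp on a small fixture. What the generator does
**not** emulate: realistic sequence evolution (substitutions, indels, split
codons across introns, frame shifts), UTRs and alternative splicing,
assembly gaps, or compositional biases that shape real e-values. Passing
tests therefore demonstrate the correctness and calibration of the
clustering and testing machinery under the stated null and planted
alternatives — not alignment quality on real genomes.

Validation sizes were chosen to exercise the statistics at desk scale: 100
noise replicates of 200 hits for the family-wise error rate (bound
`α + 3·SE`), 20 replicates × 3 planted blocks of 6 gene pairs for recovery
(≥ 90%), pools of 5000 for the CLT cross-check, and 50 paired runs for
early-stopping consistency.

# Numerical and design choices

* **Coordinates** are 1-based inclusive everywhere internally — the
  IRanges/GFF3 convention; BED output converts on write. A single convention
  end to end is how this package avoids off-by-one ambiguity in the distance
  arithmetic.
* **CDS over exon**: when a gene has CDS features they define the translated
  intervals (with frame from the CDS phase); otherwise exon features with
  frame 0 are used. The choice clips UTRs where annotation allows it.
  Features shared by splice variants are deduplicated by
  (scaffold, interval, strand, frame). Internal stop codons are kept as `*`:
  the aligner, not the parser, judges homology.
* **Bi-directional merge**: a hit requires the exon pair in both directions
  with mutually overlapping aligned intervals; the footprint is the
  intersection, the e-value the maximum (conservative). Pairs seen one-way
  are dropped. Multiple reciprocal local alignments yield multiple hits.
* **Hits with `E ≥ 1`** score `K = 0` but are retained: they still occupy
  the pools and can be the (zero-cost) best hit of an unaccounted exon.
* **Unaccounted** means fully contained in the cluster span and untouched by
  its hits; exons straddling the span boundary are not counted, since
  partial-overlap counting would penalize every cluster edge.
* **Tie-breaking** in single linkage (equal merge distances) picks the pair
  whose smallest member hit id is smallest, hit ids being assigned in
  (scaffold, start) order — so trees, and everything downstream, are
  reproducible across platforms and input orderings.
* **Strand** does not enter the distance: hits between opposite-strand exons
  cluster with the rest, as the distance is purely positional.
* **Degenerate inputs**: empty hit sets refuse a null model; single-hit
  scaffold pairs form one-leaf trees that the two-gene rule excludes;
  permutation draw requests beyond a pool's size truncate to the pool (the
  finite-population factor then contributes zero variance).
* **CLT stress-test pools** are Uniform(0, 1): a neutral, full-range quality
  distribution for validating the approximation, independent of the noise
  model.

# Known limitations

Only pairwise comparisons are supported; more than two genomes require
running all pairs. The null assumes exchangeable hit qualities — no
evolutionary structure (e.g. shuffling whole genes) — so on real genomes the
p-values are calibrated against a weaker null than one might wish, which is
exactly why the conservation-ratio threshold `τ` exists as a second,
structural filter (`τ = 1` for divergent genomes; `τ = 2` for close
strains). Alignment itself is delegated: results inherit the aligner's
e-value calibration. And the cluster score ignores exon order by design;
where order matters, a different score (and a permutation scheme that
preserves order structure) would be needed.
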