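---
title: "Clonal lineage inference for IGH repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal lineage inference for IGH repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrclone)
```

## The inference problem

An IGH repertoire is a set of heavy-chain sequences, each annotated with an
IGHV gene, an IGHJ gene and a CDR3 amino-acid sequence. Sequences descending
from the same V(D)J rearrangement (a *clonal lineage*) share those germline
segments and differ mainly by somatic hypermutation (SHM), which is
concentrated in and around the CDR3. The task is to partition the repertoire
into lineages without knowing the number of lineages, their sizes, or the
local mutation load — all of which vary over orders of magnitude between a
healthy polyclonal repertoire and a leukemic monoclonal one.

`bcrclone` treats this as a multi-objective agglomerative clustering: a
conservative pre-clustering fixes the finest admissible partition, and two
refinement passes merge — never split — clusters, balancing intra-clonal
cohesion against inter-clonal separation and penalizing leftover singletons.

## Pre-clustering

Sequences are first keyed by (IGHV gene, IGHJ gene, CDR3 length). Gene-level
comparison (allele suffix `*NN` stripped) is the default because allele
miscalls are common in practice; `allele_level = TRUE` restores strict
allele matching. Within each key group, sequences are separated when their
CDR3 amino-acid identity falls below the threshold `s` (default 0.70; both
`70` and `0.70` are accepted). Identity is positional (Hamming) because all
group members share one CDR3 length.

"Separate below s" is operationalized as single-linkage connected
components of the graph joining pairs with identity ≥ `s`. This is the
weakest splitting consistent with the rule, which matters because the
downstream stages can only merge: any over-split here is recoverable, any
over-merge is not. The boundary is strict — a pair at identity exactly
`s − ε` contributes no edge, a pair at exactly `s` does.

Indels inside the CDR3 violate the equal-length assumption. A
`cdr3_length_tolerance` hook (default 0) pools length bins within the given
tolerance and switches identity to `1 −` normalized Levenshtein; it is off
by default because no general tolerance works across repertoires, but it is
the right switch when a lineage is known to carry junction indels.

Rows are treated as clonotypes: identical reads are expected to arrive
already collapsed with a `duplicate_count`, abundance reporting uses read
counts, and all distance computations are unweighted over rows. Clustering
duplicated reads separately would only replicate zero-distance points.
Non-productive sequences are retained — clonality diagnostics often hinge
on non-productive dominant clones.

## The composed distance

Whole-sequence distances conflate segments of very different length and
variability, so each segment gets its own distance and the results are
combined as a weighted mean:

$$d(i,j) = \frac{\alpha\, d_V + \beta\, d_{CDR3} + \lambda\, d_J}{\alpha + \beta + \lambda}.$$

Only the ratios of the coefficients matter; with $\alpha = \beta = \lambda$
this is the arithmetic mean. Four per-segment distance types are available:

* **binary** — 0 iff the two annotations are equal (after allele stripping
  at gene level). The published default for the V segment.
* **normalized Levenshtein** — edit distance divided by the longer length;
  the default for CDR3 and J.
* **k-mer** — $1 - |K_a \cap K_b| / \max(|K_a|, |K_b|)$ over distinct
  k-mers, `k = 3` by default (sensible for short CDR3 peptides). The max
  denominator (containment) is chosen so that identity gives exactly 0 and
  k-mer disjointness exactly 1; Jaccard is available behind
  `kmer_denominator = "jaccard"`.
* **GIANA-style embedding** — residues map to the leading components of an
  SVD factorization of BLOSUM62, sequences are center-padded to a common
  length, and the Euclidean distance is rescaled to [0, 1] by
  $\sqrt{L}\,\max_{a,b}\lVert e_a - e_b\rVert$. This is a deliberate
  simplification of the original isometric encoding (whose exact transform
  is not public in a reimplementable form); it preserves the properties the
  clustering relies on ($d(a,a)=0$, symmetry, substitution-aware
  similarity) and is excluded from the default configuration.

For the V and J segments the configured metric applies to the annotation
strings (gene labels) — the distance step has no germline sequences to
align, and the default configuration uses the binary V distance anyway.

Per-segment distances are computed once per unique annotation value and
reused, so repeated pairs are bit-identical within a run.

## Refinement: cohesion vs separation

For each sequence $i$ in a cluster $k$ with $|k| > 1$, two silhouette-style
terms are computed: $a_i$, the mean composed distance to the other members
of $k$, and $b_i$, the smallest *mean* distance to the members of any other
cluster. A sequence with $a_i > b_i$ sits closer to another cluster than to
its own — an inconsistency — and its cluster is merged with the nearest
cluster (the argmin of the mean distance, ties to the smallest label).

Two readings of $b_i$ are possible (minimum over single distances vs
smallest average); the average is used because it is the silhouette-
consistent definition and the only one that makes $a_i > b_i$ a
cohesion/separation test rather than a nearest-neighbour test. A cluster
containing one duplicate of $i$ plus one remote sequence yields
$b_i = 0.5$, not $0$.

Scheduling: clusters are visited in ascending label order, members in input
order; the first violation triggers an immediate merge and a fresh pass, so
all terms are recomputed after every merge. The iteration stops when a full
pass finds no violation, or after `max_iter` (default 1000) passes — a cap
that is never reached in practice since each pass merges two clusters. The
first-violation schedule makes results deterministic for a given input
order; it also means the output can depend on row order for ambiguous
configurations, which is inherent to any greedy merge cascade.

## Singleton absorption

Singletons cannot trigger the $a_i > b_i$ test ($a_i$ is undefined), yet
most of them are stray lineage members. Each singleton (ascending label
order) finds the cluster minimizing the mean distance to its sequence and
joins it iff the cluster's *uniformity* changes by less than `delta`
(default 0.05):

$$\mathrm{unif}(k) = \sum_{i \in k} \frac{\lvert \mathrm{local\_den}(i) - \mathrm{avg\_den}(k) \rvert}{\mathrm{avg\_den}(k)}, \qquad
\mathrm{local\_den}(i) = \min_{j \in k,\, j \ne i} d(i,j).$$

Written with signed deviations the sum is identically zero (deviations from
a mean cancel), which cannot be the intended variability measure; the
implementation therefore uses absolute deviations, and a `literal = TRUE`
flag restores the signed form for auditing. Two degenerate cases are
defined to 0: singletons, and clusters whose average local density is 0
(all duplicate clonotypes — perfectly uniform). Merges apply immediately,
so later singletons see enlarged clusters; this maximizes absorption, which
is the stage's purpose. The absorption pass runs once, after refinement has
converged, matching the two-step design; alternating the two stages to
joint convergence was considered and rejected as unspecified and rarely
different in outcome.

With `delta = 0` nothing merges (the test is a strict inequality), which is
the intended off switch.

## The benchmark simulator

The simulator produces what the clustering pipeline needs to be tested
against: repertoires whose true lineage structure is known exactly.

* **Germline pool.** A bundled synthetic set (20 V, 12 D, 8 J genes;
  files named `synthetic_germlines_*.fasta`) stands in for a database
  download. V genes are in-frame, stop-free, and end with the conserved
  cysteine codon; J genes carry the conserved tryptophan anchor at a
  recorded offset. User FASTA pools are accepted with the same contract.
* **Junction formation.** V is used in full; D is trimmed 0–5 nt per side;
  J is trimmed 0–5 nt at its 5' end; N1/N2 insertions are uniform 0–10 nt
  of uniform bases. The N2 length is then padded mod 3 so the J anchor
  stays in the V reading frame. Real rearrangements are frequently
  out of frame; constraining the simulation to in-frame junctions costs no
  generality for a benchmark that keeps only productive sequences, and it
  keeps the CDR3 well-defined for every descendant (coordinates are fixed
  because SHM is modelled as substitutions only).
* **Lineage growth.** A Galton–Watson tree: each node draws
  Poisson($\lambda$) offspring ($\lambda = 2$ by default). Each offspring
  receives $m \sim$ Poisson($\mu_0 \lambda_0$) point substitutions at
  positions drawn proportionally to per-site mutabilities, where $\mu_0$ is
  the parent's mean mutability. $\lambda_0$ defaults to 0.26 with
  benchmark grid $\{0.16, 0.26, 0.36, 0.46\}$ — higher values produce more
  divergent lineages. No selection model is applied.
* **SHM targeting.** The default mutability model raises the mutable base
  of the classic WRC/GYW hotspot motifs to weight 5 (baseline 1); a
  published 5-mer table can replace it via `read_s5f()`. The closed form of
  the default model ($\mu_0 = (l - h + hw)/l$ for $h$ hotspot centers) makes
  the mutation-load law directly testable.
* **Assembly.** Sequences whose translation contains a stop codon are
  discarded; lineages are subsampled to a clonality profile — monoclonal:
  the top lineage holds ≥ 70% of sequences (34 lineages by default);
  oligoclonal: two dominant lineages at 14% and 9% (43 lineages);
  polyclonal: every lineage ≤ 5% (44 lineages, even split). Minor-lineage
  quotas are spread evenly; infeasible profiles (e.g. a polyclonal cap
  violated by the even split) are rejected rather than silently adjusted.

What the simulator does **not** emulate: sequencing error, junction indels
during SHM, clonal selection, isotypes, light chains, or annotation error —
the V/D/J calls attached to simulated reads are the true picks, i.e. the
benchmark assumes a perfect annotator. Perfect F-scores on these benchmarks
therefore show that the clustering logic recovers well-separated lineage
structure, not that the pipeline is robust to annotation noise or indels;
those failure modes must be assessed on real data.

Benchmark sizes used in the shipped tests and the acceptance script
(~1000 sequences, 20–44 lineages) match the simulated-benchmark scale the
method was designed around; the test suite additionally uses 100–300
sequence repertoires where the property under test does not depend on
scale.

## Evaluation

Two complementary accuracy views, both precision/recall/F over
TP/FP/FN sets:

* **pairwise** — over all unordered sequence pairs: together in truth and
  inference (TP), together only in inference (FP), together only in truth
  (FN). Counted via the contingency table ($\sum \binom{n_{ij}}{2}$ — the
  test suite checks this against explicit enumeration).
* **closeness** — inferred and truth clusters are matched one-to-one by
  shared-sequence count; each matched pair contributes $|I \cap T|$ to TP,
  $|I \setminus T|$ to FP, $|T \setminus I|$ to FN; unmatched clusters
  contribute nothing. This mode tracks repertoire structure: splitting a
  dominant clone hurts it far more than pairwise counting suggests.

Matching is greedy by descending overlap (ties: larger truth cluster, then
lexicographic labels), which is deterministic and fast. Greedy matching can
be suboptimal on heavily confused partitions, so an exact maximum-overlap
assignment (bitmask dynamic programming) is available via
`method = "optimal"` for small instances; on truth-like inferences the two
agree. Zero-denominator conventions: precision is 0 when TP+FP = 0, recall
0 when TP+FN = 0, F 0 when p + r = 0.

`compare_distributions()` labels every cluster of one distribution against
another with five mutually exclusive events — identical, join (exact union
of ≥ 2 whole clusters), split (proper subset of one cluster), mix, not
found (contains foreign sequences) — with precedence not-found → identical
→ join → split → mix, which makes the classification total. Counts are
reported raw; both possible percentage denominators (either distribution's
cluster count) can be formed from them.

Clonality is summarized by the mean-absolute-difference Gini coefficient of
cluster sizes and the Lorenz curve (least-to-most abundant); the identity
Gini = 1 − 2·AUC(Lorenz) holds exactly for the implemented forms and is
asserted numerically in the tests.

## Parameter grid

`grid_configs()` enumerates pre-clustering thresholds {50…90%} × 4 metric
choices per segment (4³ = 64) × 7 coefficient schemes × singleton merge
on/off — 4480 configurations. The seven default schemes are the arithmetic
mean plus the six distinct 2/1 emphases of one or two segments
(`d211`, `d121`, `d112`, `d221`, `d212`, `d122`); the exact historical
seven are not documented anywhere reimplementable, so the grid accepts
arbitrary user-supplied schemes as well. `grid_run()` executes a grid (or
any subset) over named benchmarks and returns a tidy results table;
`grid_plan()` reports the planned run count (53760 for the full grid on 12
benchmarks) before committing to a computation of that size.

## Defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `s` | 0.70 | CDR3 identity threshold (fraction or percent) |
| V / CDR3 / J metric | binary / Levenshtein / Levenshtein | per-segment distances |
| `alpha, beta, lambda` | 1, 1, 1 | arithmetic mean of segment distances |
| `kmer_k` | 3 | amino-acid k-mer size |
| `delta` | 0.05 | singleton-absorption uniformity tolerance |
| `max_iter` | 1000 | refinement pass cap |
| `lambda` (simulator) | 2 | offspring Poisson rate |
| `lambda0` (simulator) | 0.26 | baseline mutation rate |
| hotspot weight | 5 | WRC/GYW mutability multiplier |

## Known limitations

* Distances use gene labels, not germline sequences, for V and J; a
  Levenshtein distance between gene *names* is a label heuristic, not a
  sequence alignment (the default V metric is binary, so this only affects
  non-default configurations).
* The full composed-distance matrix is materialized, so memory grows
  quadratically with unique clonotypes; repertoires beyond ~20k unique
  clonotypes need blocking or pre-deduplication upstream.
* The greedy merge cascade is input-order-dependent in ambiguous
  configurations; runs are reproducible for a fixed input.
* CDR3 indels within a lineage split it at pre-clustering unless
  `cdr3_length_tolerance` is raised.
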