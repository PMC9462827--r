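# bcrclone

Infer B-cell clonal lineages from annotated immunoglobulin heavy-chain (IGH)
repertoires, benchmark the inference on simulated repertoires with known
truth, and quantify repertoire clonality.

## The problem

After V(D)J recombination, each naive B cell carries a unique heavy-chain
rearrangement; antigen-driven somatic hypermutation (SHM) then diversifies
the descendants of each founding cell. A *clonal lineage* is the set of all
sequences descending from one rearrangement event. Grouping the reads of a
sequenced repertoire into clonal lineages is the first step of most
repertoire analyses (clonality diagnostics, lineage-tree reconstruction,
antigen-response tracking), and it is hard precisely because SHM makes
clonally related sequences differ while unrelated rearrangements can look
similar.

`bcrclone` implements a multi-objective agglomerative approach for users of
AIRR-format rearrangement tables (any V(D)J annotation tool works upstream):

1. **Pre-clustering.** Sequences with the same IGHV gene, the same IGHJ gene
   and the same CDR3 length are grouped; each group is split at a CDR3
   amino-acid identity threshold *s* (default 70%) by single linkage —
   sequences below *s* identity to every member of a component are
   separated.
2. **Refinement.** Using the composed distance

   d(i,j) = (α·d_V + β·d_CDR3 + λ·d_J) / (α + β + λ),

   with per-segment distances chosen among binary, normalized Levenshtein,
   k-mer and an embedding (GIANA-style) distance, the silhouette terms
   a_i (mean intra-clonal distance) and b_i (smallest mean distance to
   another cluster) flag inconsistencies: any sequence with a_i > b_i
   triggers a merge of its cluster with its nearest cluster, iterated to a
   fixed point.
3. **Singleton absorption.** Each singleton joins its closest cluster iff
   the cluster's *uniformity* — the normalized dispersion of
   nearest-neighbour distances, unif(k) = Σ_i |local_den(i) − avg_den(k)| /
   avg_den(k) — changes by less than δ (default 0.05).

The package also ships:

* a **benchmark simulator**: synthetic germline V/D/J pool, random junction
  formation (N insertions, exonuclease trims), Galton–Watson lineage growth
  (offspring ~ Poisson(λ)), hotspot-biased SHM (per-offspring mutation load
  ~ Poisson(μ₀λ₀), WRC/GYW targeting), productive-only filtering, and
  assembly into monoclonal / oligoclonal / polyclonal repertoires with
  ground-truth lineage labels;
* **evaluation metrics**: pairwise and closeness precision / recall /
  F-score against truth, a five-event comparison of two clonal
  distributions (identical / join / split / mix / not found), and Gini /
  Lorenz clonality summaries;
* a **parameter-grid runner** spanning thresholds × per-segment metrics ×
  coefficient schemes × singleton settings (4480 configurations by
  default), and a thin CLI (`inst/cli/bcrclone`) with `run`, `simulate`,
  `grid`, `evaluate` and `compare` subcommands.

## Worked example

```r
library(bcrclone)

# a truth-labelled oligoclonal benchmark: 500 sequences, 20 lineages,
# two dominant lineages at 14% and 9%
sim <- simulate_repertoire("oligoclonal", target_size = 500,
                           n_lineages = 20, seed = 42)

fit <- cluster_lineages(sim$repertoire)   # default parameters
#> pre-clustering: 20 initial clusters
#> refinement: 0 merges in 1 passes -> 20 clusters
#> singleton absorption: 0 singletons merged -> 20 clusters

fit
#> <clonal_clustering> 500 sequences in 20 clonal lineages
#>   pre-clusters: 20; after refinement: 20 (0 merges, 1 passes); singletons absorbed: 0
#>   largest lineage: 70 sequences (14.0%); singletons: 0

glance(fit)
#> # A tibble: 1 x 7
#>   n_sequences n_clusters n_singletons largest_fraction  gini refine_iterations
#> 1         500         20            0             0.14 0.140                 1

evaluate_clustering(sim$truth, fit$clustering)$metrics
#> # A tibble: 2 x 7
#>   mode      precision recall fscore    tp    fp    fn
#> 1 pairwise          1      1      1  7332     0     0
#> 2 closeness         1      1      1   500     0     0
```

The pipeline recovers all 20 simulated lineages exactly: every one of the
7332 clonally related sequence pairs is co-clustered (pairwise mode) and
every matched lineage is sequence-identical to its truth counterpart
(closeness mode). `tidy(fit)` gives the per-sequence assignment,
`autoplot(fit)` a rank-abundance view, and `write_clustering()` exports the
AIRR table with a `clone_id` column plus a per-cluster summary.

Real data enters through `read_airr("rearrangements.tsv")`, which keeps
rows carrying a V call, a J call and a CDR3/junction amino-acid sequence
and reports what it dropped.

## Documentation

The methods vignette (`vignettes/clonal-lineage-inference.Rmd`) describes
the model, every tunable parameter with its default and rationale, what the
simulator does and does not emulate, and the numerical edge-case policies.
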