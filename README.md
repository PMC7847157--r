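# funalign

Supervised cross-species network alignment and GO-term transfer.

## The problem

Given two protein–protein interaction (PPI) networks *G₁(V₁, E₁)* and
*G₂(V₂, E₂)* and a set of cross-species **anchor links** (sequence-similar
protein pairs, e.g. BLASTP hits at E ≤ 10⁻⁷), the goal is a many-to-many
alignment *R ⊆ V₁ × V₂* that links functionally corresponding proteins, so
Gene Ontology annotations can be transferred from the better-annotated
species to the other. Instead of assuming that topological similarity
implies functional similarity, `funalign` *learns* the correspondence:

1. **Ground truth.** A cross-species pair is *functionally related* when it
   shares ≥ *k* GO terms under experimental evidence codes (EXP, IDA, IPI,
   IMP, IGI, IEP), biological-process aspect, and an optional term-rarity
   threshold (terms annotating ≤ *r* proteins); *unrelated* when it shares
   no GO term of any kind.
2. **Features.** The two networks are integrated through the anchors into
   one heterogeneous graph. Per-node features are either 15-dimensional
   graphlet orbit signatures (exact induced counts of the 2–4-node
   graphlets, orbit 0 = degree) or skip-gram embeddings of random walks —
   unconstrained second-order walks, or metapath-constrained walks that
   alternate species and are forced across anchors.
3. **Classification.** Each ground-truth dataset is balanced by
   undersampling negatives (10 replicates), split *y*%/(100−*y*)% with
   class stratification (10 splits; the first split is seed 0), and an
   L2-penalised logistic regression is scored by accuracy and AUROC,
   averaged over splits then over replicates.
4. **Alignment & transfer.** The alignment is the first split's *testing*
   pairs predicted related — so it can never contain a trained-on pair.
   For each relevant GO term *g*, the four counts *M* (eligible
   cross-species pairs), *N ⊆ M* (pairs sharing *g*), *O* (eligible
   aligned pairs) and *P ⊆ O* (aligned pairs sharing *g*) feed the
   hypergeometric upper tail P[X ≥ |P|], X ~ Hypergeom(|M|, |N|, |O|);
   enriched terms (p < 0.05) are transferred across the alignment.
5. **Consensus.** Intersecting the prediction sets of a graphlet pipeline
   and an embedding pipeline yields the high-precision consensus output.

A synthetic-world generator (`generate_world()`) plants cross-species
functional modules with tunable density, annotation dropout, anchor
fidelity and noise, so the entire pipeline is testable without downloads.

## Worked example

```r
library(funalign)
library(dplyr)

world <- generate_world(synth_config(seed = 1))
world
#> <synth_world: 65+64 nodes, 114+115 edges, 153 anchors, 189 annotation records>

build_ground_truth(world$annotations, world$network1, world$network2,
                   k = 1, rarity = "ALL")
#> <ground_truth k=1 rarity=ALL: 184 positive / 3870 negative pairs, 43 relevant terms>

grid <- experiment_grid(
  feature_versions = c("graphlets_integrated", "metapath_walks"),
  y = c(50L, 90L), n_replicates = 3L, n_splits = 3L,
  walk = walk_params(walks_per_node = 10, walk_length = 30, dim = 32,
                     window = 5, epochs = 5, seed = 7))
ex <- run_experiment(world$network1, world$network2, world$anchors,
                     world$annotations, grid)

tidy(ex)   # final (two-level averaged) classification scores
#> # A tibble: 4 × 7
#>   version                  k rarity     y accuracy auroc n_missing_auroc
#>   <chr>                <int> <chr>  <int>    <dbl> <dbl>           <int>
#> 1 graphlets_integrated     1 ALL       50    0.752 0.817               0
#> 2 graphlets_integrated     1 ALL       90    0.728 0.776               0
#> 3 metapath_walks           1 ALL       50    0.972 0.992               0
#> 4 metapath_walks           1 ALL       90    0.972 0.991               0

ex$predictions |>
  group_by(version, y) |>
  summarise(precision = mean(precision), recall = mean(recall),
            n_predictions = round(mean(n_predictions)), .groups = "drop")
#> # A tibble: 6 × 5
#>   version                  y precision recall n_predictions
#>   <chr>                <int>     <dbl>  <dbl>         <dbl>
#> 1 consensus               50     0.853  0.736           145
#> 2 consensus               90     0.922  0.210            38
#> 3 graphlets_integrated    50     0.541  0.736           229
#> 4 graphlets_integrated    90     0.747  0.210            48
#> 5 metapath_walks          50     0.833  0.810           163
#> 6 metapath_walks          90     0.917  0.262            48
```

Reading the numbers: on this planted-module world the metapath-walk
features recover the functional signal almost perfectly (AUROC ≈ 0.99),
while graphlet features saturate near 0.8 — local topology alone cannot
tell *which* module a dense neighbourhood belongs to. Transfer precision
rises with the training percentage (larger *y* → smaller, more confident
alignments) while recall falls, and the consensus is more precise than
either source at the cost of recall, which is bounded by each source's.
`autoplot(ex)`, `plot_prediction_metrics(ex)` and
`autoplot(noise_sweep(...))` draw the corresponding figures.

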