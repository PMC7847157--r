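---
title: "Supervised cross-species network alignment and functional transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised cross-species network alignment and functional transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funalign)
```

## The problem

Given two protein–protein interaction (PPI) networks \(G_1(V_1, E_1)\) and
\(G_2(V_2, E_2)\) from different species, network alignment seeks a relation
\(R \subseteq V_1 \times V_2\) linking proteins that play corresponding
roles, so that functional knowledge (Gene Ontology annotations) can be
transferred from the better-annotated species to the other. Classical
aligners score topological similarity and assume that similar wiring implies
similar function. `funalign` instead *learns* what functional
correspondence looks like: cross-species protein pairs with known shared
function become positive training examples, pairs with provably disjoint
function become negatives, and a classifier over network-derived pair
features decides which held-out pairs belong in the alignment.

Two sources of information enter the features. Within-network topology is
summarised per node; across-network sequence similarity enters through
*anchor links* — cross-species protein pairs with strong sequence similarity
(e.g. BLASTP hits at \(E \le 10^{-7}\)) — which are added as edges to form a
single *integrated network* over \(V_1 \cup V_2\). Features extracted from
the integrated network therefore mix both signals.

## Ground truth: functionally related and unrelated pairs

Functional relatedness is defined from GO annotations restricted to
experimentally supported evidence codes (EXP, IDA, IPI, IMP, IGI, IEP) and
the biological-process aspect. A cross-species pair is *related* when the
two proteins share at least \(k\) qualifying GO terms (\(k = 1, 2, 3\)), and
*unrelated* when they share no GO term *of any kind* — any aspect, any
evidence, including electronic annotations. Pairs sharing only
non-qualifying terms receive neither label and are excluded; this asymmetry
makes the negative class conservative.

Because generic high-level GO terms annotate hundreds of proteins and carry
little specificity, a *rarity threshold* \(r\) optionally removes every term
annotating more than \(r\) distinct proteins (both species combined,
counting only network proteins); the bound is inclusive, and `r = "ALL"`
disables it. Crossing \(k \in \{1,2,3\}\) with \(r \in \{\mathrm{ALL}, 50,
25\}\) yields the nine ground truth–rarity datasets the evaluation grid
walks. Only direct annotations are used — the package never reasons over
the GO hierarchy, so a parent term shared via propagation does not make a
pair related. `label_pairs()` exposes the two annotation views separately,
so a propagation step can be inserted upstream if desired.

## Pair features

**Graphlet orbit signatures.** For every node we count exact induced
occurrences of each automorphism orbit of the connected 2–4-node graphlets
(15 orbits; orbit 0 is the degree). Counting uses the ESU connected-subgraph
enumeration algorithm with degree-sequence classification, which is exact —
3- and 4-node connected graphs are uniquely identified by their degree
sequences. We cap graphlets at 4 nodes: the 15-orbit signature keeps an
exhaustive brute-force test oracle feasible while already distinguishing
paths, stars, cycles and cliques; the counter is a single function behind
which a larger orbit basis could be swapped. A pair's feature vector is the
ordered concatenation of the two nodes' signatures, each coordinate
log-transformed (\(\log(c+1)\)) to tame heavy-tailed counts. Counting runs
either on the two networks separately (`graphlets_isolated`, topology only)
or on the integrated network (`graphlets_integrated`, topology + sequence).
Edge types are ignored during counting: typed (heterogeneous) graphlets
explode combinatorially and are out of scope.

**Random-walk embeddings.** `generate_walks()` produces second-order biased
walks (return parameter \(p\), in–out parameter \(q\); \(p = q = 1\) gives
first-order uniform walks), and `generate_metapath_walks()` constrains each
step's node *type* to a cyclic metapath — the default `c(1, 2, 1)`
alternates species, forcing every second step across an anchor, so the
embedding geometry is dominated by cross-species correspondence.
`train_embedding()` fits skip-gram with negative sampling over the walk
corpus (Rcpp, single-threaded, explicitly seeded: identical seeds give
identical embeddings). Defaults follow the published node2vec settings
(`r = 10` walks of length 80 per node, `d = 128`, window 10); tests and the
bundled experiments shrink these (`d` 16–32, length 15–30) because synthetic
worlds have ~100 nodes, not \(10^4\).

**Combining two embeddings into a pair feature.** The elementary operation
`pair_feature_embedding()` defaults to ordered concatenation, with the
Hadamard (elementwise) product as the alternative. The *pipeline* default is
Hadamard (`experiment_grid(embedding_combiner = "hadamard")`), and the
choice matters: a logistic regression over concatenated coordinates cannot
express "these two points are close" — embedding spaces are
rotation-symmetric, so no linear functional of \((e_u \,\|\, e_v)\) encodes
proximity — whereas the Hadamard product makes the model a weighted inner
product, exactly the standard recipe for link prediction with embeddings.
On planted-module worlds the difference is between near-chance and
near-perfect classification.

## Classification protocol

Unrelated pairs vastly outnumber related ones, so each ground-truth dataset
is rebalanced: a *balanced dataset* keeps all positives plus an equal-size
uniform subsample of negatives, and 10 such replicates (seeds
`balanced_seed + i`) average out the subsampling. Each balanced dataset is
split \(y\%\) training / \((100-y)\%\) testing, class-stratified so both
sides stay 50/50, 10 times (split \(j\) uses seed `split_seed + j`; the
"first" split is \(j = 0\), i.e. seed 0 under the defaults). The classifier
is an L2-penalised logistic regression (glmnet ridge with
\(\lambda = 1/(nC)\), \(C = 1\), unstandardised features, deterministic
coordinate descent); the penalty matters because small balanced splits with
30–64-dimensional features separate perfectly and unpenalised maximum
likelihood diverges. Accuracy (threshold 0.5) and AUROC (midrank ties) are
averaged in two levels — over the 10 splits within a replicate, then over
the 10 replicates — giving one final score per (feature version, dataset,
\(y\)); \(y\) runs from 10 to 90 in steps of 10.

The *alignment* for a given (version, dataset, \(y\), replicate) is the set
of first-split testing pairs predicted related (probability ≥ 0.5). Using
the testing side only is the anti-circularity guarantee: an alignment can
never contain a trained-on pair, and `build_alignment()` both checks the
model/split provenance and asserts the empty intersection. Three feature
versions × nine \(y\) values × ten replicates give 270 alignments per
ground-truth dataset. Cells whose positive class is too small to survive
stratified splitting at every requested \(y\) are skipped and recorded.

## Functional transfer and the consensus ensemble

Given an alignment \(A\) and the relevant GO terms of the ground
truth–rarity dataset, a protein is *eligible* when it carries at least
\(k\) relevant terms. For each relevant term \(g\), four counts feed a
hypergeometric upper-tail test: \(M\) (all cross-species pairs of eligible
proteins), \(N \subseteq M\) (pairs where both carry \(g\)),
\(O \subseteq A\) (aligned pairs of eligible proteins) and
\(P \subseteq O\) (aligned pairs where both carry \(g\)). The p-value is
\(\Pr[X \ge |P|]\) for \(X \sim \mathrm{Hypergeom}(|M|, |N|, |O|)\) —
computed with `stats::phyper(P-1, N, M-N, O, lower.tail = FALSE)` and
cross-checked in the tests against exhaustive enumeration of all
\(\binom{M}{O}\) draws. A term with \(p < \alpha\) (default
\(\alpha = 0.05\), raw; the enrichment convention of established
transfer frameworks, configurable) is transferred: every eligible aligned
protein whose alignment partner carries \(g\) is predicted to carry \(g\).
A protein's own annotation never triggers its own prediction — the term
must arrive from across the alignment — and since alignments exclude
training pairs, no prediction can be traced solely to a trained-on pair.

Precision is the fraction of predicted (protein, term) associations present
in the ground-truth dataset; recall is the fraction of ground-truth
associations recovered, over associations whose protein is a network node.
Because up to \(y\%\) of the data was used for training, a recall of 1 is
structurally unreachable; `precision_recall()` can report the
attainable-recall ceiling alongside. An empty prediction set reports
precision 1 (with a message) in the elementary function — there are no
wrong predictions — but aggregate sweeps score it 0 (`empty_as`), since
"no correct prediction" is the honest summary of a failed run.

Two feature pipelines err differently; intersecting their prediction sets
(`intersect_predictions()`) keeps only associations both support. This
consensus is the package's highest-precision output; its recall is bounded
by each source's recall (a subset property the tests assert). The default
pairing intersects a graphlet version with an embedding version.

## The synthetic world generator

`generate_world()` plants `n_modules` functional modules, each present in
both species: members interact at `p_intra = 0.8` within their module over
a `p_background = 0.02` background, carry the module's GO terms
(experimental evidence, aspect P) with 10% dropout, and anchors join
cross-species same-module pairs at rate 0.7 plus ~0.3 random pairs per
species-1 node. Defaults use 8 modules of 4–6 proteins per species plus 25
background proteins per species — large enough for a few hundred labeled
pairs, small enough that exact graphlet counting and an exhaustive test
oracle stay fast. Background proteins receive private singleton terms
(annotated but unshareable) and a fraction of all proteins a common
cellular-component IEA term, so all three labeling outcomes occur. The
generator emulates the *logic* of the real inputs, not their statistics: no
scale-free degree tails, no GO hierarchy, no correlated annotation biases.
Passing tests therefore demonstrate correctness of the machinery and
recoverability of planted signal, not performance on real proteomes.

`inject_noise(f)` randomises a fraction `f` of every data layer:
degree-preserving double-edge swaps on each network (swapping until at most
\((1-f)|E|\) original edges survive), uniform re-targeting of `f` of the
anchors, and uniform re-assignment of `f` of the annotation records to
random same-species proteins. Degrees, edge counts, anchor counts and
record counts are all preserved, so only *structure* is destroyed.
`noise_sweep()` scores the noised pipeline's predictions against the
*clean* world's ground truth — the fixed external knowledge a noised run is
trying to recover. This matters: if only edges and anchors were noised, the
balanced testing sets (built from intact annotations) would still contain
50% truly related pairs and transfer precision would plateau near 0.5
instead of decaying; with all layers noised and clean-truth scoring,
precision and recall fall monotonically and approach zero at 100% noise.

## Numerical and design choices

* **Seeds.** Every stochastic layer (generator, balanced subsampling,
  splits, walks, skip-gram) takes an explicit seed and restores the
  caller's RNG state; single-worker training is the reproducibility mode.
* **Namespacing.** Node IDs are namespaced `"<species>:<raw id>"` inside
  the integrated network, making the disjoint-ID assumption enforceable;
  raw IDs are preserved in all user-facing tables.
* **Degenerate inputs.** Empty edge files warn and return empty networks;
  anchors with unknown endpoints are dropped and counted; single-class
  test sets yield `NA` AUROC, excluded from means with a logged count;
  infeasible splits raise errors that the grid runner converts into
  recorded skips.
* **Decision threshold** 0.5 on the predicted probability — for binary
  logistic regression this coincides with the argmax rule.
* **Problem sizes.** The bundled experiments and tests run worlds of
  roughly 60–130 nodes per species, embedding dimensions 16–32 and walk
  lengths 15–30; all reported numbers in the README come from these sizes.

## Limitations

Homogeneous graphlet features cannot tell *which* module a dense
neighbourhood belongs to, so topology-only versions saturate well below the
embedding versions on planted worlds; the same limitation motivates the
integrated (anchored) variants. The hypergeometric test is applied per term
without multiple-testing correction, matching the transfer-framework
convention but inflating enriched-term counts at small \(\alpha\) margins.
The generator's independence assumptions (uniform anchors, independent
dropout) make the synthetic task easier than real cross-species transfer;
absolute precision/recall values here do not forecast performance on real
yeast–human data.
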