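---
title: "Positive-unlabeled graph learning for disease protein prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positive-unlabeled graph learning for disease protein prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pugnn)
```

## The problem

Most disease-protein discovery settings provide a short list of proteins with
positive evidence and a proteome-wide pool of uncharacterized candidates —
but no reliable negatives, because absence of evidence is not evidence of
absence. Conventional supervised classification is therefore inapplicable.
`pugnn` implements a positive-unlabeled (PU) learning framework that scores
every node of a protein–protein interaction (PPI) network by combining two
information sources: frozen per-protein feature vectors (in real use,
precomputed language-model embeddings of sequence and functional text) and
the interaction topology itself, fused by a graph convolutional scorer
trained under PU objectives.

## Data model

A `PPINetwork` stores a deduplicated, self-loop-free undirected graph. Edges
with STRING-style confidence at or below the threshold (default: strictly
above 700 on the 0–1000 scale) are discarded and the largest connected
component is kept, because message passing and random-walk propagation need
a connected substrate. Node order is canonical — lexicographically sorted
IDs — and every downstream matrix is row-aligned to it, which makes all
artifacts byte-reproducible. Edge confidences are retained as metadata but
aggregation is deliberately unweighted.

A `LabelSet` partitions the nodes into labeled positives and unlabeled; a
`FeatureMatrix` is an ordinary numeric matrix aligned to the node order and
is never updated during training (the embedding extractors are frozen; the
learnable surface is only the network head described next).

## The scorer

The scorer is a 3-layer graph convolutional network over the
symmetric-normalized adjacency with self-loops,

$$\hat A = \tilde D^{-1/2} (A + I)\, \tilde D^{-1/2},$$

with each layer applying conv → batch normalization → ReLU → dropout
(p = 0.5), and a final fully connected layer with a sigmoid producing one
score per node in (0, 1). Scores are ranking scores, not calibrated
probabilities. Design choices the architecture leaves open were fixed as
follows:

* **Layer order.** "Normalization after each layer" is ambiguous; we use
  conv → BN → ReLU → dropout, the common arrangement that keeps the
  pre-activation distribution standardized.
* **Hidden widths** default to (128, 32, 16), tapering toward the scalar
  output; the widths are free parameters of `initGCN()` and chosen so a
  full sweep of the protocol stays cheap on a single CPU.
* **Initialization** is uniform Glorot (fan-scaled), deterministic in the
  run seed.
* **Full-batch training.** The whole graph is one batch (a few thousand to
  ~10⁴ nodes fits comfortably), so the batch statistics *are* the population
  statistics. Evaluation and checkpointing therefore normalize by the
  full-graph statistics and sync them into the stored running statistics.
  The usual exponential running average (momentum 0.1) needs ~15 epochs to
  catch up with the fast-moving early-training statistics, and
  model-selecting on its lagged outputs produced a spurious early-recall dip
  that could trigger premature early stopping.
* **Identity ablation.** Substituting the identity for $\hat A$ turns the
  scorer into a plain MLP on the features; the feature-only baseline and the
  mixup virtual nodes (which have no graph position) use this path.

Training is full-batch Adam (lr 0.001) for at most 250 epochs with early
stopping (patience 10), implemented with hand-derived backpropagation
through the conv/BN/ReLU/dropout stack (verified against numerical
differentiation in the test suite).

## The four PU objectives

All four share the generalized PU risk decomposition

$$R_{PU}(f) = \pi_p\, E_P[\ell(f,1)] + \big\{ E_U[\ell(f,0)] -
\pi_p\, E_P[\ell(f,0)] \big\},$$

where $\ell$ is binary cross-entropy on scores clipped to
$[\varepsilon, 1-\varepsilon]$ ($\varepsilon = 10^{-7}$), $\pi_p$ the class
prior, and the bracket is the surrogate negative risk estimated from the
unlabeled pool and corrected for its hidden positives.

* **nnPU** clamps the surrogate negative risk at zero (fixed prior 0.10).
  When the clamp engages, the default "defensive" update descends on the
  violation instead of freezing (switchable via `puLossConfig(defensive=)`).
* **Dist-PU** (fixed prior 0.10) uses $E_P[\ell(f,1)]$ plus a label
  distribution alignment term $|E_U[\sigma]-\pi_p|$, entropy minimization on
  unlabeled scores ($\lambda_{ent}=0.1$) and mixup regularization
  ($\lambda_{mix}=0.1$, $\lambda\sim\mathrm{Beta}(1,1)$, one virtual node
  per unlabeled node per epoch, pairs drawn uniformly from $P\cup U$ with
  interpolated pseudo-labels, unlabeled treated as 0).
* **PU-GNN** is nnPU with a dual prior schedule (0.5 for the first 20
  warm-up epochs, then 0.1) plus an edge-smoothness penalty
  $\lambda\,\mathrm{mean}_{(i,j)\in E} (\sigma_i-\sigma_j)^2$
  ($\lambda=0.1$) that propagates positive signal along interactions.
* **GRAB** needs no assumed prior: one belief sweep
  $b_i \leftarrow (1-\beta)\,\sigma_i + \beta\,\mathrm{mean}_{j\in N(i)} b_j$
  per epoch ($\beta = 0.5$, labeled positives pinned at 1, beliefs carried
  across epochs), a dynamic prior equal to the fraction of refined unlabeled
  beliefs above 0.5 clamped to [0.001, 0.05], and nnPU in which unlabeled
  nodes with belief > 0.5 join the positive-side means as provisional
  positives while remaining in the unlabeled means — they gain a
  prior-weighted upward pull but still feel the unlabeled-as-negative push,
  so transient belief errors decay instead of ratcheting (removing them
  from the unlabeled pool lets several hundred background nodes saturate
  near score 1 and destroys the ranking). Beliefs are constants w.r.t. the
  parameters. The Dist-PU and
  GRAB renditions follow the published descriptions of those methods, not
  any particular reference codebase.

## Spy evaluation and model selection

Because no test negatives exist, sensitivity is measured with spies: 5-fold
cross-validation over the *positives* hides 20% of them per fold inside the
unlabeled pool and measures their recovery, $\mathrm{Recall} = TP/(TP+FN)$
with "recovered" meaning score strictly above 0.5. SCAR labeling in the
synthetic generator makes the underlying selected-completely-at-random
assumption true by construction.

Per-epoch model selection and early stopping track the **mean spy rank**
(rescaled to [0, 1], higher is better) rather than threshold spy recall.
Threshold recall is trivially maximized — an untrained model whose randomly
initialized readout happens to score most nodes above 0.5 achieves spy
recall 1.0 at epoch 1, after which no improvement is possible and the
patience rule halts training on garbage scores (observed at some seeds).
The spies' mean rank instead measures the ordering that the downstream
consensus actually consumes, improves smoothly while the ranking sharpens,
and plateaus naturally; a minimum improvement of `minDelta` (default 1e-3,
i.e. about two rank positions per spy on a 2,000-node graph) is required to
reset the patience counter, so micro-gains do not stretch training to the
epoch cap. Threshold spy recall (score strictly above 0.5) remains the
reported metric and the consensus weight below. Surrogate F1 is reported
alongside.

Fold scores are combined into a **recall-weighted consensus**
$c_i = \sum_f r_f s_{i,f} / \sum_f r_f$ over the unlabeled pool (descending,
ties by node ID), each model keeps its top 100, and the union across the
four models — with per-model membership flags — forms the candidate pool.

## Enrichment-based refinement

Candidates are tested per annotation category (tissue, GO BP/MF/CC,
pathway) by the upper-tail hypergeometric test against the full network as
background, BH-corrected within category. A term is retained when FDR ≤
0.001, fold enrichment > 1, foreground count ≥ 5 and background count ≤ the
cap. The background cap scales with network size
(`round(nNodes * 500/8300)`, i.e. 500 at the reference full scale of 8,300
nodes), so the same filter logic applies to desk-scale synthetic networks.
A candidate survives refinement iff it is covered by at least one retained
term in *every* category that has retained terms (vacuous categories are
skipped); the per-candidate coverage report makes the alternative reading
(intersecting retained term member lists directly) auditable.

## Baselines and topology profiling

Three non-PU comparators isolate the contribution of each modality: random
walk with restart from the labeled positives (restart 0.15, tol 1e-8,
column-normalized transitions — classic propagation defaults), the
feature-only MLP (identity operator, nnPU loss), and a graph-only GCN whose
features are four z-scored topology descriptors (degree, local clustering,
core number, mean neighbor degree — the concrete descriptor set is our
choice). `topologyReport()` profiles candidates by degree, normalized
betweenness (Brandes fractional tie-splitting, pair-count denominator —
chosen because reported magnitudes of ~10⁻² on ~10⁴-node graphs are only
plausible under normalization), local clustering, and the known-positive
neighbor ratio.

## The synthetic generator

`simulatePUData()` emulates the study conditions at desk scale:

| parameter | default | meaning |
|---|---|---|
| `nNodes` | 2000 | preferential-attachment graph (connected, heavy-tailed) |
| `attachM` | 3 | edges per new node; ~6k edges, mean degree ~6 |
| `moduleSize` | 60 | planted true-positive module |
| `rewireIntoModule` | 1.0 | one extra intra-module edge per module node |
| `nFeatures` / `nInformative` | 64 / 16 | feature width / informative columns |
| `effectSize` | 1.0 | mean shift of informative columns for true positives |
| `labelFrac` | 0.6 | SCAR-labeled fraction of true positives |
| `seed` | 42 | master seed; all generators derive their streams from it |

`rewireIntoModule` is set to the top of its range: with weaker module
cohesion, neighbor aggregation dilutes the feature signal faster than the
graph contributes information, and the fused models fall below the
feature-only ablation — the opposite of the complementary-signal regime the
generator is meant to represent. Annotation sets contain one signal term per
category (the module plus noise members) among random terms whose sizes
straddle the scaled background cap.

What the generator does *not* emulate: language-model embedding geometry
(features are Gaussian), confidence-score distributions (synthetic edges all
carry 999), tissue specificity, and literature-driven labeling bias (labels
are SCAR by construction, which real curated labels are not). Passing tests
on this fixture therefore demonstrates correctness of the machinery and the
qualitative method ordering, not real-data effect sizes.

## Numerical and degenerate-input choices

* Score clipping $\varepsilon=10^{-7}$ keeps all losses finite; gradients
  vanish outside the clip window.
* GRAB's dynamic prior floor (0.001) guards epochs where nothing crosses
  threshold; its cap (0.05) is part of the method definition.
* Consensus requires at least one fold with positive recall
  (otherwise: "no informative folds").
* Ranking ties break by ascending node ID; duplicate edges collapse to the
  maximum confidence; an exactly-threshold score counts as not recovered.
* Early stopping measures "no improvement" strictly; with constant
  validation performance training stops after 1 + patience epochs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full protocol on the
2,000-node reference fixture (three run seeds), plus a 250-node fixture for
protocol mechanics; oracle cross-checks enumerate all connected graphs on
≤ 6 nodes for betweenness, all count tuples with background ≤ 12 for the
hypergeometric tail, and 20 random 30-node graphs for the random walk.
Small fixtures use a larger learning rate (0.005–0.02), since at a few
hundred nodes the reference rate does not move the scores measurably within
the patience window.

## Known limitations

* The spy protocol estimates sensitivity only; precision is a prior-derived
  surrogate, so reported surrogate F1 inherits any prior misspecification.
* Best-epoch selection on spy performance mildly inflates spy recall
  relative to an untouched validation set (selection bias over ~tens of
  epochs); training-set recall can therefore appear lower than spy recall
  on easy fixtures.
* Fold-level metrics are not independent samples; no significance testing
  across models is performed or implied.
* GRAB's provisional-positive rendition dilutes the positive-risk gradient
  early in training; it recovers, but remains the weakest ranker of the
  four on the synthetic fixture.
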