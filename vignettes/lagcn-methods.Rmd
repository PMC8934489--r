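---
title: "Layer-attention graph convolution for miRNA-disease association prediction: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layer-attention graph convolution for miRNA-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagcn)
```

## The problem

MicroRNAs (miRNAs) are short non-coding RNAs that regulate gene
expression, and their dysregulation is implicated in many complex
diseases. Curated catalogues such as HMDD record experimentally
supported miRNA-disease associations, but they are sparse: the v2.0
regime this package targets has 5430 known associations between 495
miRNAs and 383 diseases, about 2.9% of all pairs. The task is link
prediction on this bipartite network: score every unobserved pair so
that true-but-unrecorded associations rank highly.

The guiding assumption is homophily — miRNAs with similar function tend
to associate with phenotypically similar diseases. The model therefore
works on a *heterogeneous* network that joins three edge sets:
miRNA-miRNA similarity, disease-disease similarity, and the known
associations.

## The model

**Input network.** With `N` the binary `n_m x n_d` association matrix,
`S^m` and `S^d` the within-type similarity matrices, and a penalty
factor `mu` (hyperparameter name `simw`) controlling how strongly
similarity edges contribute, the adjacency and the initial node
features are

    A = [ mu*S^m   N    ]        X0 = [ 0     N ]
        [ N^T      mu*S^d ]           [ N^T   0 ]

over `n_m + n_d` nodes (miRNAs first). `mu = 0` is the
associations-only ablation. Each node's initial feature vector is its
binary association profile.

**Encoder.** Three graph-convolution layers under symmetric Laplacian
normalisation `Ahat = D^{-1/2} A D^{-1/2}`:

    X^(l+1) = ReLU( Ahat %*% X^(l) %*% W^(l) )

with no bias terms. The normalised operator has spectral radius at most
1, which keeps repeated propagation stable. Zero-degree nodes (possible
only at `mu = 0`) get zero rows/columns in `Ahat` by defining the
degree-inverse as 0 — no self-loops are added, because the
unit-diagonal similarity blocks already supply diagonal mass at
`mu > 0`, and adding them would change the ablation being measured.

**Layer attention.** The three layer embeddings capture neighbourhoods
of increasing radius; rather than keeping only the last, they are fused
by a learned convex weighting `Z = sum_l softmax(alpha)_l X^(l)`. The
logits `alpha` are trainable and initialised to zero (uniform weights).
Softmax parameterisation guarantees the fused embedding stays in the
element-wise convex hull of the layer embeddings and makes the scores
invariant to shifting all logits.

**Decoder.** Scores are bilinear-logistic:
`a' = sigmoid(Z_m %*% W_dec %*% t(Z_d))` with `Z_m`, `Z_d` the miRNA
and disease blocks of `Z`. The functional form of the decoder is a
genuinely open design point in this model family; we default to the
bilinear decoder with trainable `W_dec` (the richer, lineage-standard
choice) and expose `decoder = "inner"` (`W_dec = I`, frozen) as an
ablation. Only layers 1..L are fused; `X^(0)` is excluded because the
fusion is defined over embeddings produced by the propagation rule.

**Loss.** Full-graph imbalance-weighted cross-entropy over all
`A x B = n_m * n_d` cells,

    Loss = -(1/(A*B)) * ( lambda * sum_{y+} log a' + sum_{y-} log(1 - a') )

with `lambda = |y-|/|y+|`, the negative/positive cell ratio of the
*training* matrix (about 33.9 at catalogue scale). No negative sampling
is used — the `1/(A*B)` normalisation already implies every cell enters
each epoch. Scores are clipped to `[1e-10, 1 - 1e-10]` before the
logarithms, which are undefined at the endpoints.

**Optimisation.** Adam at learning rate 0.01 for 250 epochs, full-graph
steps, no schedule, early stopping or weight decay. The optimizer
family is a design choice recorded in every CV report; Adam is the
default of this model lineage. Gradients are exact analytic backprop
through decoder, attention softmax, dropout masks and the ReLU layers;
the test suite verifies them against central finite differences.

**The two dropouts.** `adjdp` (default 0.6) is symmetric edge dropout
on `Ahat`, redrawn every epoch: entries are zeroed in (i,j)/(j,i) pairs
and survivors rescaled by `1/(1 - rate)`, so the operator is unbiased
in expectation. `dp` (default 0.4) is ordinary element dropout applied
to each layer embedding; the dropped embedding feeds both the next
layer and the attention fusion. Both are training-only; inference is
deterministic.

## Hyperparameters

| name      | meaning                              | default | notes |
|-----------|--------------------------------------|---------|-------|
| `epoch`   | full-graph gradient steps            | 250     | fixed budget, no early stopping |
| `emb_dim` | embedding width                      | 64      | |
| `lr`      | Adam learning rate                   | 0.01    | larger values trade AUC for recall |
| `adjdp`   | edge dropout on `Ahat`               | 0.6     | per-epoch symmetric mask |
| `dp`      | element dropout on embeddings        | 0.4     | |
| `simw`    | similarity penalty `mu`              | 6       | 0 = associations-only ablation |
| `layers`  | convolution layers                   | 3       | |
| `threshold` | score cut for recall/accuracy      | 0.5     | the canonical cut on a logistic score; the metrics literature for this task usually leaves the threshold unstated |

## Cross-validation protocol

Known positives are partitioned uniformly at random into five
near-equal folds. For each fold the held-out positives are set to zero
in the association matrix, and the heterogeneous network is *rebuilt
from the masked matrix*, so a test edge is invisible to the encoder as
well as to the loss — scoring edges the encoder has seen would be
leakage, and an assertion scans every fold for it at run time. Test
instances are the masked positives (label 1) against **all**
never-positive cells (label 0), with no negative sampling; this makes
the high accuracy values interpretable, since ~97% of cells are
negative. Metrics are AUC (Mann-Whitney midrank form, ties counted
half), recall and accuracy at the threshold.

All randomness — fold assignment, weight initialisation, both dropouts
— derives from one master seed through named streams, so a report is
bit-reproducible from its config echo.

## The synthetic generator

`simulate_associations()` plants the structure the model is built to
exploit: latent factors `U` (n_m x rank) and `V` (n_d x rank) with
standard normal entries, positives at the top `ceiling(density*n_m*n_d)`
cells of `U %*% t(V)` (top-k thresholding pins the positive count
exactly, making fold sizes deterministic), and similarity matrices that
are Gaussian kernels on the factor rows (bandwidth `1/rank`, so typical
factor distances give mid-range similarities), blended towards the
identity by `similarity_noise`. Similarities built from the same
factors encode the homophily assumption; at `similarity_noise = 1` they
are pure identity and carry no signal.

Defaults emulate the catalogue regime (2.9-5% density, low rank). What
the generator does *not* emulate: the heavy-tailed degree distribution
of real catalogues, literature-driven ascertainment bias, block
structure from disease ontologies, or any sequence-level content.
Passing the recovery tests therefore shows the pipeline can detect
planted low-rank homophily, not that it reproduces the published
real-data AUC, which depends on similarity constructions deferred to
external sources.

Problem sizes used by the tests and the acceptance script were chosen
as the smallest that exercise every code path at stable statistics: the
recovery setting is a 120 x 90 network (rank 4, density 0.05,
similarity noise 0.2) under 100-epoch, 5-fold CV over three master
seeds, and one full-scale run (495 x 383, 250 epochs, width 64) checks
the published dimensions end to end.

## Numerical choices and degenerate inputs

- Score clipping at `1e-10` from each end before logarithms.
- Zero-degree guard: `D^{-1/2}` entry defined as 0; rows/columns of
  `Ahat` become zero instead of NaN.
- Similarity validation: asymmetry up to `1e-6` is averaged away,
  beyond that rejected; out-of-range values are clamped to [0, 1] with
  a warning (published similarity files often carry rounding
  overshoot); the diagonal is forced to 1.
- Ties at the top-k cut of the generator are broken deterministically
  so the positive count is exact.
- Glorot uniform initialisation; attention logits start at zero.
- `epoch = 0` returns the initialised model untouched.
- All matrices are dense: at 878 nodes dense BLAS is fast (a full
  250-epoch run takes well under a minute) and avoids sparse/dense
  dialect bugs. A sparse path is out of scope.

## Known limitations

- The real-data similarity constructions (miRNA functional similarity,
  DAG-based disease semantic similarity) are not computed here; the
  package accepts them as files and offers the Gaussian interaction
  profile kernel as a self-contained fallback. Published real-data
  metrics depend on that choice.
- Full-graph training only; no mini-batching or GPU path.
- Binary associations only; weighted catalogues are out of scope.
- Deep stacks over-smooth: embeddings of all nodes converge with many
  layers. Three layers with layer attention is the mitigation used
  here, not a solution.
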