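# lagcn

Link prediction of miRNA-disease associations with a layer-attention
graph convolutional network (LAGCN).

MicroRNAs regulate gene expression, and their dysregulation is tied to
many complex diseases, but curated catalogues of experimentally
supported miRNA-disease associations are sparse (~3% of pairs at HMDD
v2.0 scale: 5430 associations between 495 miRNAs and 383 diseases).
This package is for computational biologists who want to prioritise
unobserved pairs for experimental follow-up by exploiting homophily:
similar miRNAs tend to associate with similar diseases.

## The model

Known associations `N`, miRNA similarity `S^m` and disease similarity
`S^d` are stacked into one heterogeneous network with a penalty factor
μ (`simw`) weighting the similarity edges:

```
A = [ μ·S^m   N     ]      X⁰ = [ 0    N ]      Â = D^{-1/2} A D^{-1/2}
    [ N^T     μ·S^d ]           [ N^T  0 ]
```

A three-layer graph convolutional encoder propagates the features,

```
X^(l+1) = ReLU( Â X^(l) W^(l) ),
```

a learned softmax attention fuses the layer embeddings,
`Z = Σ_l softmax(α)_l X^(l)`, and a bilinear logistic decoder scores
every pair, `a′ = sigmoid(Z_m W_dec Z_dᵀ)`. Training minimises the
imbalance-weighted cross-entropy over all A×B cells,

```
Loss = -(1/(A·B)) ( λ Σ_{y⁺} log a′ + Σ_{y⁻} log(1 − a′) ),   λ = |y⁻|/|y⁺|,
```

with Adam (lr 0.01, 250 epochs), symmetric edge dropout on Â
(`adjdp = 0.6`) and element dropout on the embeddings (`dp = 0.4`).
Forward and backward passes are exact dense linear algebra written in
R and verified against finite differences in the test suite.
Evaluation is masked five-fold cross-validation: held-out positives are
removed from the adjacency *and* the loss, then scored against all
never-positive cells with AUC, recall and accuracy.

## Worked example

```r
library(lagcn)

sim <- simulate_associations(120, 90, rank = 4, density = 0.05,
                             similarity_noise = 0.2, seed = 7)
net <- build_network(sim$n, sim$s_m, sim$s_d, mu = 6)
cfg <- lagcn_config(epoch = 100, seed = 7)

fit <- lagcn_train(net, cfg)
fit
#> LAGCN fit: 3 GCN layers, emb_dim 64 , bilinear decoder
#>   network: 120 miRNAs x 90 diseases; lambda = 19
#>   loss: 1.3164 -> 0.61547 over 100 epochs

predict_ranked(fit, net, top = 5)
#> # A tibble: 5 × 4
#>   mirna   disease     score known
#>   <chr>   <chr>       <dbl> <lgl>
#> 1 mir-013 disease-079 0.991 FALSE
#> 2 mir-022 disease-018 0.978 FALSE
#> 3 mir-074 disease-022 0.974 FALSE
#> 4 mir-009 disease-022 0.974 FALSE
#> 5 mir-098 disease-004 0.971 FALSE

cv <- lagcn_cv(sim$n, sim$s_m, sim$s_d, cfg, k = 5)
cv
#> 5-fold cross-validation (master seed 7)
#> # A tibble: 3 × 3
#>   metric    mean     sd
#>   <chr>    <dbl>  <dbl>
#> 1 accuracy 0.896 0.0205
#> 2 auc      0.960 0.0157
#> 3 recall   0.869 0.108
```

The loss falls from 1.32 to 0.62 over training; the held-out AUC of
0.96 says a random true association outranks a random non-association
96% of the time on this planted-structure data. `tidy()`, `glance()`
and `autoplot()` methods expose the loss trace and fold metrics as
tibbles and ggplots. On real catalogue data, pass your own similarity
matrices (`read_similarity()`) or use the Gaussian interaction profile
fallback (`similarity_fallback = "gip"`).

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lagcn.R", package = "lagcn"))')" \
  simulate --n-mirna 120 --n-disease 90 --density 0.05 --seed 7 --out sim/
# then: build | train | cv | predict, see --help
```

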