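# molfuse

Molecular property prediction from SMILES with three complementary
encoders and generative self-supervised pretraining.

Labeled molecular property data (solubility, permeability, toxicity
panels) are scarce; unlabeled SMILES are abundant. `molfuse` pretrains
three encoders on unlabeled molecules — a bidirectional LSTM and a
Transformer over the SMILES token sequence, and a two-layer graph
attention network (GAT) over the molecular graph — and fine-tunes them,
combined by hierarchical attention-weighted feature fusion, for downstream
regression and multi-task classification.

## The model

Each encoder pools a molecule to a feature in a shared space
$\mathbb{R}^d$: $h_x$ (BiLSTM), $h_y$ (Transformer), $h_z$ (GAT). In
pretraining every view gets a VAE head — a posterior
$(\mu, \log\sigma^2)$, a reparameterized latent
$z = \mu + \sigma \odot \epsilon$, and a projector $q(\cdot)$ back to
$\mathbb{R}^d$ — and views are trained in pairs:

$$
L_{ab} = \tfrac12\big[\lVert q_a(z_a) - \mathrm{SG}(h_b)\rVert^2
       + \lVert q_b(z_b) - \mathrm{SG}(h_a)\rVert^2\big]
       + \tfrac{\beta}{2}\big[\mathrm{KL}_a + \mathrm{KL}_b\big],
\qquad
L = \mathrm{mean}(L_{xy}, L_{xz}, L_{yz}),
$$

with $\mathrm{SG}$ the stop-gradient operator and each KL the closed-form
divergence of the posterior from a standard-normal prior. Downstream, the
sequence features are fused first and the result is fused with the graph
feature; each fusion block computes a sigmoid-convolutional weight matrix
$W$ and returns
$\mathrm{FC}(h_a \odot W + h_a) + \mathrm{FC}(h_b \odot (1-W) + h_b)$, the
weight on the second feature being the exact complement $1 - W$. Metrics
follow benchmark conventions: RMSE for regression, mean rank-statistic
ROC-AUC over evaluable tasks for classification, with missing labels
masked throughout.

Everything runs on a small reverse-mode autodiff engine in plain R (no
deep-learning framework); gradients are tested against finite differences
and every architectural block against an independent brute-force oracle.

## Worked example

```r
library(molfuse)

corpus <- generate_corpus(60, seed = 1)     # valid synthetic SMILES
head(corpus, 3)
#> [1] "c1ccccc1CNCN" "CC"    "OCONC"

cfg <- molfuse_config(d = 16L, n_heads = 2L, epochs = 5L,
                      batch_size = 16L, seed = 1L)
pt <- pretrain(corpus, cfg)
glance(pt)
#> # A tibble: 1 × 5
#>   n_molecules epochs best_epoch best_loss final_loss
#> 1          60      5          5      5.73       5.73

data <- make_regression_dataset(generate_corpus(120, seed = 2),
                                coeffs = c(1, 0), noise_sd = 0.5, seed = 3)
model <- finetune(pt, data,
                  config = molfuse_config(d = 16L, n_heads = 2L,
                                          epochs = 4L, batch_size = 16L,
                                          seed = 1L))
evaluate_model(model, data)
#> # A tibble: 3 × 4
#>   partition     n metric value
#> 1 train        96 rmse    4.36
#> 2 valid        12 rmse    3.27
#> 3 test         12 rmse    3.26

predict(model, c("CCO", "c1ccccc1CCN"))
#> # A tibble: 2 × 3
#>   smiles          y .error
#> 1 CCO          4.60 <NA>
#> 2 c1ccccc1CCN  4.80 <NA>
```

The labels here are the molecules' heavy-atom counts plus noise (the
generator records its coefficients), so the short fine-tuning run is
already pulling predictions towards molecular size; longer runs at the
package defaults (`d = 64`, 20 epochs) tighten the RMSE further — the test
suite's learning-signal checks do exactly that at `d = 32` under three
seeds. Interpretability comes from atom-level Pearson similarity maps:

```r
sim <- molecule_similarity(pt, "c1ccccc1CO")
round(unclass(sim)[1:4, 1:4], 2)
#>      C1   C2   C3   C4
#> C1 1.00 0.91 0.88 0.90
#> C2 0.91 1.00 0.99 0.99
#> C3 0.88 0.99 1.00 1.00
#> C4 0.90 0.99 1.00 1.00
render_heatmap(sim, "similarity.png")
```

Datasets load from MoleculeNet-style CSVs (`read_property_csv()`, blank
cells = missing labels), split randomly or by Bemis–Murcko scaffold with
zero scaffold leakage (`random_split()`, `scaffold_split()`), and every
stage is scriptable from a shell via `exec/molfuse
<pretrain|finetune|predict|ablate|heatmap|synth> config.yaml`. The
ablation harness (`run_ablation()`) covers pretraining-pair subsets,
downstream encoder subsets, fusion vs plain concatenation, and corpus-size
sweeps.

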