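---
title: "Methods: triple-encoder generative self-supervised molecular representation learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple-encoder generative self-supervised molecular representation learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(molfuse)
```

## The problem and the model

Predicting molecular properties (solubility, permeability, toxicity panels)
from structure is central to early drug discovery, and labeled data are
scarce relative to the millions of unlabeled SMILES strings in public
compound databases. `molfuse` addresses this with self-supervised
pretraining over unlabeled molecules followed by supervised fine-tuning.

A molecule enters the model through two complementary representations:

* the **SMILES token sequence**, read by a bidirectional LSTM and by a
  Transformer encoder, giving molecule features $h_x$ and $h_y$;
* the **molecular graph** (heavy atoms as nodes, bonds as directed edge
  pairs), read by a two-layer graph attention network (GAT), giving $h_z$.

All three features live in a shared space $\mathbb{R}^d$ — the pretraining
objective compares features across views, which forces a common dimension.

### Generative pairwise pretraining

Each view gets a VAE head. A posterior MLP maps the pooled feature to a
diagonal Gaussian $(\mu, \log\sigma^2)$, a latent is drawn by
reparameterization $z = \mu + \sigma \odot \epsilon$, and a projector MLP
$q(\cdot)$ maps $z$ back into $\mathbb{R}^d$. For a pair of views $(a, b)$
the loss is

$$
L_{ab} = \tfrac12\left[\lVert q_a(z_a) - \mathrm{SG}(h_b)\rVert^2
       + \lVert q_b(z_b) - \mathrm{SG}(h_a)\rVert^2\right]
       + \tfrac{\beta}{2}\left[\mathrm{KL}_a + \mathrm{KL}_b\right],
$$

where $\mathrm{SG}$ is the stop-gradient operator (the target feature is a
constant for that term) and each KL is the closed-form divergence of the
posterior from the standard-normal prior,
$\tfrac12\sum(\mu^2 + \sigma^2 - 1 - \log\sigma^2)$. The total objective is
the arithmetic mean of the three pairwise losses $L_{xy}, L_{xz}, L_{yz}$.
Maximizing agreement between each view's generative reconstruction and the
other views' features is a variational surrogate for maximizing the mutual
information between views: molecules whose sequence and graph descriptions
carry consistent information should produce mutually predictable features.

Decisions the objective's description left open, fixed here once:

* the prior is standard normal, making the KL closed-form;
* the head predicts the log-variance (the numerically stable choice);
* one $\epsilon$ draw per view per step, shared by that view's two pair
  terms;
* the additive constant of the reconstruction lower bound is dropped;
* the printed form of the pairwise objective has inconsistent
  subscripts/norm exponents in its source; the symmetric reading above is
  used;
* $\beta$ defaults to 0.1 (configurable); the objective's source introduces
  $\beta$ without a value.

### Encoders

**BiLSTM.** Gate equations in the standard form: sigmoid forget/input/output
gates over $[h_{t-1}, x_t]$, $C_t = f \odot C_{t-1} + i \odot \tilde C_t$,
$h_t = o \odot \tanh C_t$. The molecule feature concatenates the two
directions' final hidden states and maps them linearly to $d$; per-token
unit features do the same per position.

**Transformer.** Embedding, additive fixed sinusoidal position encoding (the
canonical choice; only the existence of a position term was specified),
multi-head scaled dot-product self-attention
$\mathrm{softmax}(QK^\top/\sqrt{d_k})V$, residual connection with layer
normalization, then a two-linear feed-forward block with ReLU. Two layers
and four heads by default. Pooling to molecule level is a masked mean over
positions followed by a linear map (the sequence-to-molecule pooling was
unspecified; the BiLSTM already contributes a recurrence-based summary, so
the Transformer uses the simplest permutation-respecting alternative).

**GAT.** Edge logits $e_{ij} = \mathrm{LeakyReLU}(a^\top[Wh_i \| Wh_j])$
(slope 0.2), softmax-normalized over each neighborhood, aggregation
$h_i' = \sigma(\sum_j a_{ij} W h_j)$ with $\sigma = \mathrm{ELU}$ and a
single attention head (the original GAT defaults). Self-loops are added to
every node so no softmax neighborhood is empty. Exactly two layers; the
molecule feature is an elementwise max over atoms followed by a two-layer
MLP.

In training, a batch is processed as one concatenated sequence/graph with a
block-diagonal attention mask, which is mathematically identical to
per-molecule processing (verified by the batch-independence tests) but far
cheaper in R.

### Hierarchical elem-feature fusion

Downstream, the two sequence features are fused first, then the result with
the graph feature, by structurally identical but unshared blocks. A block
stacks the two features as a two-channel map, applies a 3×3 convolution
(padding 1) to one channel, and a sigmoid yields a weight matrix
$W \in (0,1)$; the output is
$\mathrm{FC}(h_a \odot W + h_a) + \mathrm{FC}(h_b \odot (1-W) + h_b)$ with
FC = linear + ReLU. The two branch weights are exact elementwise
complements.

One geometry decision deserves a note. Fusion operates on molecule-level
features, so each molecule's stacked map is a $1 \times d$ two-channel
image: the kernel's vertical taps always fall on zero padding, and
convolution runs along the feature dimension only. The alternative —
convolving across the batch dimension — would make a molecule's prediction
depend on its batch neighbors, violating batch independence, which this
package treats as non-negotiable for a predictor. A concatenation + linear
fallback (`fusion = "concat"`) is retained as the ablation baseline.

### Fine-tuning

All parameters (encoders, fusion, head) are updated; nothing is frozen —
with molecule counts in the hundreds-to-thousands, full fine-tuning is the
safer default and matches the package's learning-signal tests. Losses are
masked mean squared error (regression) and masked elementwise binary
cross-entropy with logits (multi-task classification); missing labels
contribute nothing. Model selection takes the epoch with the best
validation metric (lowest RMSE / highest mean AUC). Metrics follow the
benchmark conventions: RMSE for regression, and a rank-statistic ROC-AUC
per task averaged arithmetically over evaluable tasks for classification;
tasks with one class after masking are skipped with a warning.

## The numerical substrate

No deep-learning framework is part of the package's dependency set; the
entire model runs on a small reverse-mode automatic differentiation engine
over dense matrices (`R/autodiff.R`) with an Adam optimizer. The engine's
gradients are property-tested against central finite differences, and each
architectural block is tested against an independent brute-force oracle
written from the defining equations. Numerical choices: layer-norm epsilon
1e-5; stable BCE-with-logits ($\max(l,0) - ly + \log(1+e^{-|l|})$); softmax
rows shifted by their maximum; fully masked softmax rows return zeros
rather than NaN; the max-pool routes gradient to the first argmax on ties.

## Data handling

**Tokenizer.** A regex tokenizer with bracket atoms, the two-letter
elements Cl/Br, `%nn` ring closures and single-symbol tokens; token
concatenation reproduces the input exactly, and the atom mask marks atom
tokens in the left-to-right order that the graph builder also uses, so
sequence positions and graph nodes align by construction. Sequences longer
than `max_len` (default 256) are rejected, never truncated — truncation
would silently corrupt the atom mask.

**Graphs.** Heavy atoms only (hydrogens implicit). Atom features are a
minimal standard set: element one-hot over {C, N, O, S, F, Cl, Br, P, I,
other}, degree one-hot (0–5), aromatic flag. The upstream description
never lists its features; this choice is declared, not inferred.

**Scaffold split.** Molecules are grouped by Bemis–Murcko framework
(iteratively pruning terminal atoms leaves ring systems plus linkers) under
a Weisfeiler–Lehman canonical key, and whole groups fill train, then
validation, then test, largest group first (ties by key — deterministic).
No scaffold ever spans partitions; a group larger than a partition's quota
overflows it rather than being divided.

## The synthetic data generator

Tests and the acceptance script never download anything; corpora come from
a small grammar — an optional aromatic benzene fragment, an aliphatic chain
over {C, N, O} with carbon weighted 3:1, and optional single-atom branches —
so every string is valid by construction and structure is known exactly.
Default knobs: 12 heavy atoms maximum, ring probability 0.4, branch
probability 0.3, values a medicinal chemist would recognize as small
drug-like fragments. Labels are structural: regression labels are a linear
function of heavy-atom and ring counts plus Gaussian noise; classification
labels are the has-ring or has-heteroatom predicate.

What this emulates — and what it does not: the corpus has realistic token
and graph structure but nothing like real chemical-space diversity, and the
labels are exactly recoverable from structure by design. Passing the
learning-signal tests therefore shows the pipeline can extract structural
signal end to end; it says nothing about accuracy on real benchmark
endpoints, which require large-corpus pretraining at a scale outside a test
suite.

## Study scales and seeds

The package's learning-signal checks run at a deliberate desk scale, stated
here as the package's own choices: feature dimension $d = 32$, two
Transformer layers; pretraining on 200 generated molecules for 20 epochs;
regression fine-tuning on 500 molecules whose label is the heavy-atom count
plus $\mathcal{N}(0, 0.25)$ noise, compared against predicting the train
mean; has-ring classification on 300 molecules. Each check runs under three
seeds and must succeed in the majority. Defaults elsewhere: $d = 64$,
Adam with learning rate 1e-3, batch size 32.

## Known limitations

* The tokenizer and graph builder cover the organic subset plus bracket
  atoms — sufficient for the generator and common benchmark SMILES — but
  not stereochemistry-aware (stereo markers parse as plain bonds) and not a
  full aromatic-perception engine: aromaticity is read from lowercase
  notation, not derived.
* The scaffold key is a WL refinement hash, not a canonical SMILES; WL
  collisions between non-isomorphic frameworks are theoretically possible
  though not observed at molecular scaffold sizes.
* Training is CPU-bound, single-threaded R; the engine is meant for the
  reduced scales above, not for hundreds of thousands of molecules.
* Per-atom features from the sequence encoders use atom-masked token
  positions; bracket atoms contribute one position regardless of their
  internal annotations.
* The pairwise reconstruction objective has no feature normalization, so
  the scale of the stop-gradient targets can drift during training and the
  epoch loss need not fall monotonically; on small corpora an occasional
  seed shows transient loss growth before recovering. The best-loss
  checkpoint (not the final epoch) is what fine-tuning consumes, which
  absorbs this.
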