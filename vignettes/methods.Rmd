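---
title: "Methods: multi-view graph transformer for driver-gene prioritization"
author: "driverfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view graph transformer for driver-gene prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Cancer driver genes — genes whose alterations confer a selective growth
advantage to tumor cells — are prioritized here by transductive node
classification over three node-aligned biological networks: physical
protein–protein interactions (PPI), Gene Ontology semantic similarity, and
pathway co-occurrence. Each relation type carries complementary evidence;
none alone suffices. The model fuses them:

1. **Multi-view graph encoding.** Each view $G^{(m)}$ is encoded by its own
   two-layer graph convolution over the shared z-scored multi-omics feature
   matrix $X \in \mathbb{R}^{N \times F}$ (per gene: mutation rate,
   differential methylation and differential expression across cancer
   types; $F = 48$ in the reference layout):
   $Z^{(m)} = \hat A^{(m)}\,\mathrm{ReLU}(\hat A^{(m)} X W_1^{(m)})\,W_2^{(m)}$,
   with $\hat A = D^{-1/2}(A + I)D^{-1/2}$. A learnable vector
   $a \in \mathbb{R}^d$ scores each view per gene,
   $\alpha_i = \mathrm{softmax}(Z_i a) \in \mathbb{R}^3$, and the fused
   embedding is the $\alpha$-weighted convex combination of the three view
   embeddings. The $\alpha_i$ are retained as the per-gene modality weights
   for interpretability.
2. **Functional embedding from gene sets.** With binary membership
   $M \in \{0,1\}^{N \times S}$ over curated gene sets (cancer-keyword sets
   excluded to avoid label leakage), $A = \mathrm{softmax\ rows}(M W^{\mathrm{attn}})$
   and $E^{\mathrm{gene}} = A E^{\mathrm{set}}$, where both
   $W^{\mathrm{attn}} \in \mathbb{R}^{S\times S}$ and the embedding table
   $E^{\mathrm{set}} \in \mathbb{R}^{S\times d}$ are trained with the model.
3. **Structural encoding.** Two frozen inputs computed once from the PPI
   view: (i) a random-walk positional encoding — PCA scores of the
   row-stochastic transition matrix $T = D^{-1}A$, each component scaled by
   its singular value; (ii) PageRank centrality with damping 0.85. They are
   concatenated as $e^{\mathrm{struct}} = [e^{\mathrm{rw}} \mid e^{\mathrm{pr}}]$.
4. **Edge-biased transformer.** The concatenation
   $[x_i \mid z^{\mathrm{fusion}}_i \mid e^{\mathrm{gene}}_i \mid e^{\mathrm{struct}}_i]$
   is linearly projected to width $d$ and refined by $L$ post-norm
   transformer layers whose per-head pre-softmax attention logits receive an
   additive bias $b_{ij} = \sum_m \sigma(W^{\mathrm{edge}} s^{(m)}_{ij} + b^{\mathrm{edge}})$
   over the views in which the pair $(i,j)$ is connected, with the pairwise
   descriptor $s^{(m)}_{ij} = [\mathrm{score}^{(m)}_{ij},\, 1]$. A linear +
   sigmoid head yields per-gene driver probabilities.

Training minimizes focal loss
$-\alpha (1 - p_t)^\gamma \log p_t$ ($\alpha = 1$, $\gamma = 1.5$) over the
labeled genes only — unlabeled genes participate in message passing and
attention but not the loss — with AdamW (weight decay $10^{-4}$), one
full-batch gradient step per epoch. Two presets mirror the reference
hyperparameters: pan-cancer ($L=3$, $H=4$, dropout 0.1, learning rate
$10^{-3}$, 30 epochs) and cancer-specific ($L=2$, $H=2$, dropout 0.2,
learning rate $10^{-4}$, 50 epochs).

## Numerical and design choices

Where the architecture description leaves a choice open, the package fixes
one convention, documents it, and tests it:

- **Gradients.** No automatic-differentiation framework is available to R
  in the supported environment, so the package carries a small reverse-mode
  tape (`R/tape.R`). Every op and the full model gradient are verified
  against central finite differences in the test suite; the attention head
  is fused into a single op to keep the number of $N \times N$
  intermediates (the memory hot spot of full-graph attention) minimal.
- **GCN normalization** is symmetric with added self-loops,
  $c_{ij} = \sqrt{(\deg_i + 1)(\deg_j + 1)}$ — the standard reading of
  "degree-based scaling"; row normalization is available via
  `model_config(normalization = "row")`. Self-loops guarantee an embedding
  for genes isolated in a view (the GO/pathway views do not cover all
  genes). Message passing is unweighted by default; edge scores gate edge
  existence and feed the edge bias (score-weighted aggregation sits behind
  `weighted_messages = TRUE`).
- **First GCN layer maps $F \to d$.** The reference description types both
  layer weights as $d \times d$, which is inconsistent with an $F$-dimensional
  input unless features are pre-projected; resolving the input dimension to
  $F$ is the minimal consistent reading. No activation follows the second
  layer, and no dropout is used inside the GCN (dropout is specified for
  the transformer only).
- **Transformer internals** (unstated upstream): post-norm residual layout,
  feed-forward width $4d$ with GELU, layer normalization with learnable
  gain/offset, dropout on sublayer outputs during training only. One bias
  tensor $B$ is built per fit and shared across all layers. Pairs with no
  edge in any view receive bias exactly 0 ("no evidence, no modulation"),
  rather than $\sigma(b^{\mathrm{edge}})$.
- **Pairwise descriptor** $s^{(m)}_{ij}$: the upstream description names "the
  biological score and pairwise indicators" without dimensions; the package
  fixes $k = 2$ (score, existence indicator), isolated in one function so
  alternatives are drop-in.
- **Random-walk PCA**: columns are centered (standard PCA) before the
  singular decomposition; "variance-scaled" is implemented as
  singular-value scaling of the score columns (the explained-variance-ratio
  alternative would only rescale columns). Component signs are fixed so the
  largest-magnitude loading of each component is positive, making the
  encoding reproducible. Isolated nodes get a self-transition of 1 so $T$
  stays row-stochastic. `d_rw` defaults to $\min(d, N-1)$ and is
  zero-padded beyond the available rank.
- **PageRank**: uniform teleportation, dangling mass redistributed
  uniformly, power iteration to L1 tolerance $10^{-10}$ (cap 200
  iterations; non-convergence is an error reporting the residual).
- **z-scoring** uses the population standard deviation and is applied to
  the whole feature matrix once, before any train/test splitting, exactly as
  the reference protocol states. This leaks column moments across CV folds;
  the package reproduces the protocol rather than correcting it, and the
  caveat stops here. Constant columns map to zeros.
- **Focal loss** clamps probabilities at $10^{-7}$; the gradient is zero
  outside the clamp interior.
- **Initialization**: fan-in-scaled uniform for weight matrices, zeros for
  biases, ones for layer-norm gains, all drawn from seeded RNG streams.
  AdamW applies decoupled weight decay to every parameter.
- **Cross-validation** is stratified by class (essential for cancer types
  with few positives) and seeded; per-fold seeds derive from the master
  seed, so a `cv_driver_fusion` is bit-reproducible. The model used for
  ranking unlabeled genes is refit on all labeled genes after the folds.
- **Ablation switches** reuse the full code path and zero the relevant
  input block or bias: `PE` (positional encoding), `CE` (centrality), `GSA`
  (gene-set attention, parameters removed), `EAA` (edge bias = 0), `NFE`
  (fused multi-view embedding), `IF` (raw feature block). Block widths are
  preserved so parameter shapes stay comparable across variants.

## The synthetic world

`generate_dataset(synthetic_config())` produces the dataset family used for
all testing. It emulates the statistical structure the model assumes, at
desk scale:

- **Graphs**: three Chung–Lu expected-degree views (degree-heterogeneous,
  like real interactomes), with drivers' expected degree multiplied by
  `hub_bias` (default 3 — driver genes are hubs); a fraction
  `view_overlap = 0.5` of PPI edges is copied into the GO and Pathway views
  and the remainder drawn independently; edge scores are uniform above each
  view's threshold (0.85 / 0.8 / 0.6).
- **Features**: standard normal, with driver rows shifted by
  `feature_shift = 1.5` SD in a random half of the 48 columns.
- **Gene sets**: 50 sets; membership probability 0.4 for drivers vs 0.05
  baseline.
- **Labels**: 60 drivers positive and 160 sampled negatives out of 500
  genes — the 1:2.7 imbalance of the reference corpus (796:2187) at reduced
  scale — with the remainder unlabeled.

Each component draws from its own RNG stream derived from the master seed,
so regeneration is bit-identical.

One property of this world deserves emphasis: because planted drivers are
3×-degree hubs, PageRank centrality alone separates them almost perfectly
at this scale — the information channels are deliberately redundant, as
they are in real corpora. Consequently single-component ablations barely
move held-out metrics here (they matter on real, noisier data), and any
subset of channels that keeps the centrality column remains close to
ceiling; only removing the centrality channel as well produces a large
drop. The ablation machinery is therefore validated directionally (no
single ablation *gains* performance, and stripping all informative
channels collapses it), not by reproducing external ablation tables. What a green test on this world
establishes: the pipeline recovers planted signal carried by features,
topology and gene-set enrichment, the ablations behave directionally, and
everything is reproducible. What it does not establish: performance on real
corpora — the generator does not attempt STRING/CPDB topology beyond degree
heterogeneity and inter-view overlap, nor realistic feature correlation
structure, and the reference AUROC/AUPRC values from the external datasets
are out of reach at this scale by construction.

For the 500-gene synthetic world the model width is $d = 32$
($d_{\mathrm{rw}} = 16$) — a compute scaling; $d = 128$ belongs to the
$\sim$13k-gene corpora. Layer count, heads, dropout, learning rate and
epoch budget always come from the presets unchanged.

## Limitations

- Full-graph attention is $O(N^2)$ per head; `model_config(attention_cap)`
  (default 20 000) refuses larger graphs rather than silently thrashing.
- Training is full-batch R with a tape per epoch; fitting the reference
  corpora (N > 10 000, d = 128) is possible in principle but slow — this
  package targets method-level correctness and desk-scale experiments.
- The transductive design scores only genes present in the fitted graph;
  `predict()` on new universes is deliberately refused (checkpoints carry a
  universe hash).
- Symbol alias resolution is out of scope: gene identifiers are opaque
  strings, and label/feature files must use the network vocabulary.
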