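---
title: "Knowledge-oriented drug representations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-oriented drug representations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Two practical questions recur in computational pharmacology: will two
co-administered drugs interact (DDI, a binary relation), and how clinically
substitutable are two drugs (DDS, a similarity score in [0, 1])?  Both are
relational questions about *drugs as entities*, and both are easier to
answer from a good vector representation of each drug than from any single
data source.  `kmr` learns such a representation by fusing three
heterogeneous knowledge sources:

1. **Pharmacological attributes** — side effects, drug actions,
   physiological effects, pharmaceutical formulations and protein targets
   (the kind of content found in SIDER, NDF-RT and DrugBank), plus a binary
   substructure fingerprint.
2. **The drug-class taxonomy** — a rooted tree of chemical classes
   (ChemOnt-style) to which each drug attaches at a leaf.
3. **Textual descriptions** — dependency-parsed sentences about each drug,
   with drug mentions marked.

# The model

## Pharmacological block

Each attribute family is encoded as a sparse vector over the family's
catalog.  The entry for attribute $s$ of a drug that possesses $s$ is the
inverse document frequency

$$\mathrm{IDF}(s) = \log\frac{N + 1}{\mathrm{DF}(s) + 1},$$

with natural logarithm, where $N$ is the number of drugs and
$\mathrm{DF}(s)$ how many of them have $s$; all other entries are 0.  Rare
attributes are the informative ones, ubiquitous attributes get weight
exactly zero.  The five family vectors and the fingerprint bits are
concatenated in a fixed order (attribute families first, fingerprint last)
and reduced by a small convolutional encoder: a width-5, 20-channel 1-D
convolution, ReLU, max-pooling over a few contiguous segments per channel,
and a fully connected layer (500 outputs at reference scale).  Catalog
positions are frozen at training time; unseen attributes at inference are
ignored.

Three baseline reducers (plain concatenation, a fixed random mapping
matrix, a single fully connected layer) are kept for the dimensionality-
reduction comparison harness.

## Drug-class block

The taxonomy is embedded by three network-embedding channels: uniform
random walks (DeepWalk), second-order biased walks (node2vec, with return
parameter $p$ and in–out parameter $q$; the walker's unnormalized weights
are $1/p$ back to the previous node, $1$ to a common neighbor, $1/q$
otherwise), and an edge-sampling proximity objective (LINE).  Walks treat
tree edges as undirected.  Each drug is attached to its class leaf as a
node of its own, so it receives its own embedding from every channel; the
alternative of inheriting the leaf-class vector is available via
`drug_class_source = "leaf"`.  The three k-dimensional channel vectors of a
drug are stacked as the input channels of a multi-width convolution
(widths 2 and 3, 20 filters each), globally max-pooled per filter, and
projected by a fully connected layer to the class block.

Walk-based channels are trained by skip-gram with negative sampling over
the walk corpus; the trainer applies deterministic aggregated mini-batch
updates, so a fixed seed reproduces embeddings exactly.  Channel vectors
are length-normalized before use, the usual post-processing for
word2vec-family embeddings.

## Text block

Each token of a parsed sentence is embedded as the concatenation of a word
vector and four dependency-feature vectors: the token's relation to the
root (root itself / child of root / other), its relation to each of the
two marked entities (entity itself / parent of entity / child of entity /
other; a missing second entity is uniformly "other"), and its dependency
tag.  A bidirectional LSTM runs over the token sequence and its reverse;
the per-step output is the elementwise sum of the two directions.
Word-level attention (the same tanh/softmax form used in fusion, below)
pools the steps into a sentence vector; sentence-level attention scores
each sentence against a trainable query (bilinear by default, dot-product
as an option), softmax-normalizes the scores, pools the bag, and a fully
connected layer yields the text block.  Dropout (rate 0.5 at reference
settings) acts on the Bi-LSTM output layer during training only;
evaluation is deterministic.

## Interactive fusion

Each block vector is reshaped into $m$ equal column groups (default
$m = 4$) forming a matrix $H$, and attention weights are computed as

$$M = \tanh(W_{sw} H), \quad \alpha = \mathrm{softmax}(w_w^\top M), \quad
  v_c = H \alpha^\top .$$

The package exposes this composition as `attend_block()`.  For the fused
drug vector the default mode rescales each column group by $m\,\alpha_j$
and flattens, so block lengths are preserved (uniform attention is the
identity) and the fused vector is the concatenation pharm–class–text
(756 dimensions at reference scale, 500 + 128 + 128).  A pooling mode that
concatenates the $v_c$ vectors instead is available
(`fusion_mode = "pool"`).  Before fusion every block is standardized to
unit root-mean-square so the three heterogeneous sources enter on a
comparable scale.

## DDI head

The two fused drug vectors enter the joint layer as the two input
channels of a width-5, 20-filter 1-D convolution along the feature axis —
so each filter window sees the *aligned* features of both drugs, making
co-activation (shared targets, shared class) directly representable —
followed by ReLU, segment max-pooling, a fully connected layer, and the
softmax projection $y = \mathrm{softmax}(W_o\,pr + b_o)$ over
positive/negative interaction.  Predictions average both pair orderings,
so the classifier is exactly symmetric.

Training minimizes cross-entropy end-to-end through the fusion attention
and all three encoders with AdaGrad (learning rate 0.003, batch 40 at
reference settings), all parameters initialized uniformly on
$[-0.1, 0.1]$.

Two normalization choices at the joint layer were genuinely open and we
settled them empirically on synthetic data:

* The pooled convolution features and the fully connected output are
  **batch-centered with a scalar scale**: each feature is centered across
  the batch, and the whole vector is divided by one scalar, the root mean
  feature variance (running averages at evaluation, re-estimated without
  dropout after training).  Centering removes the large pair-independent
  common mode that would otherwise dominate the softmax logits — under a
  fixed small uniform initialization the offset would cost more AdaGrad
  steps than a short training run contains.  Using a *scalar* scale rather
  than per-feature whitening preserves the relative magnitudes of
  features; in our experiments full per-feature whitening destroyed the
  ranking signal (amplifying uninformative features to parity), while the
  scalar variant trains quickly and calibrates the decision threshold.
  `head_norm = "none"` disables this.
* The fully connected output feeds the softmax projection linearly (no
  ReLU); a one-sided nonlinearity there only adds a positive common mode.
* The fused drug vectors are mean-centered (batch mean during training,
  running/re-estimated mean at evaluation) before the joint convolution.
  Fused coordinates share a large drug-independent profile; without
  centering that common profile saturates or silences the ReLU'd
  convolution features and training spends most of its short AdaGrad
  budget escaping the resulting plateau.  With centering the loss
  descends from the first epoch.

## DDS head

Drug–drug similarity is predicted by a random-forest regressor (200 trees,
unlimited depth, seeded bootstraps) on the concatenation of the two fused
embeddings.  Training is two-stage: the forest fits on embeddings frozen
from a DDI-trained model.  With symmetrization both orderings enter
training and predictions average the orderings.  Forest predictions are
means of training targets, so they cannot leave the observed [0, 1] range.

# The synthetic knowledge base

No public resource is downloaded; the generator plants a known latent
structure so every stage of the pipeline is testable:

* Drugs belong to one of `n_clusters` latent mechanism clusters.  Every
  cluster owns a disjoint signature of attributes per family; a drug draws
  signature attributes with probability $1-\varepsilon$ and off-signature
  attributes with probability $\varepsilon$.  Fingerprints follow the same
  recipe over per-cluster bit blocks.
* The taxonomy is a balanced binary tree whose leaves are the clusters.
* Descriptions are template sentences ("D042 binds tg013 and causes
  se007") over the drug's own attribute tokens, with dependency trees and
  entity spans exact by construction — no parser is involved.
* A pair's DDI label is Bernoulli with
  $P = \sigma(\beta_0 + \beta_1\,\text{shared targets} +
  \beta_2\,\text{same cluster})$, defaults $\beta = (-3, 0.5, 4)$;
  similarity is the taxonomy kinship (1 same cluster, 0.5 sibling leaves,
  0 otherwise) plus Gaussian noise, clamped to [0, 1].  Labeled pairs are
  drawn half within and half across clusters, emulating the enrichment of
  curated interaction resources; with the default coefficients this gives
  a near-balanced label distribution against a 0.5 chance rate.

Study conditions used throughout the tests: 200 drugs, 8 clusters,
$\varepsilon = 0.05$, 2000 labeled pairs, 3 sentences per drug,
166 fingerprint bits.  What the generator does **not** emulate: real
marginal frequencies of side effects or targets, polysemous or noisy text,
multi-parent ontologies, and dosage- or context-dependent interactions.
Passing tests therefore demonstrate that the machinery recovers a planted
multi-source signal at desk scale, not clinical performance.

# Desk-scale configuration

`kmr_desk_config()` is the reduced profile used by the examples and the
test suite: feature blocks of 64/32/32 dimensions, Bi-LSTM hidden size 32,
word vectors of 16, walk corpora of 5 walks x 20 steps per node, 3 or 5
training epochs.  Training-regime fields keep their reference values
(kernel 5, depth 20, learning rate 0.003, batch 40, init 0.1, fully
connected sizes 500, dropout 0.5).  Dropout noise does feed the joint
layer's batch statistics during training, which is why those statistics
are re-estimated without dropout once training ends.

Numerical details worth knowing:

* All randomness flows through R's RNG; every training function takes a
  seed and is single-threaded, so results are byte-reproducible.
* Max-pool ties break to the first position; softmaxes subtract the
  maximum before exponentiation.
* Sentences longer than `max_sentence_length` (default 100) keep their
  first tokens; a sentence whose root or entity span falls outside the
  cut is dropped with a warning.
* Attribute catalogs freeze first-appearance order; vector positions are
  stable across save/load.
* The LSTM forget-gate bias initializes to 1 (on top of the uniform
  draw), the one standard exception to the uniform initialization.

# Known limitations

* The end-to-end optimizer budget at desk scale is small (a few hundred
  AdaGrad steps); runs occasionally stay on the initial plateau for a
  seed, which is why evaluation averages five seeds.
* The generator's dependency trees are short and template-derived; the
  text encoder is exercised structurally but not stressed linguistically.
* Pair-conditioned sentence bags (relation extraction proper) are out of
  scope: the text block is a per-drug description embedding.
* Probability calibration beyond what cross-entropy training provides is
  explicitly not attempted.
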