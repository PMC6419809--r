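# kmr — knowledge-oriented multimodal drug representations

`kmr` learns a single vector representation per drug by fusing three
heterogeneous knowledge sources, and uses it for two tasks:

* **DDI** — drug–drug interaction classification (softmax head, trained
  end-to-end with AdaGrad/cross-entropy);
* **DDS** — drug–drug similarity regression in [0, 1] (random-forest head
  on the frozen embeddings).

The three sources, each encoded by its own block:

1. **Pharmacology** — sparse IDF-weighted vectors over attribute catalogs
   (side effects, drug actions, physiological effects, formulations,
   targets) plus a binary substructure fingerprint, reduced by a small
   convolutional encoder.  The IDF weight of an attribute present in
   `DF` of `N` drugs is `log((N+1)/(DF+1))` (natural log).
2. **Drug class** — DeepWalk-, node2vec- and LINE-style embeddings of the
   chemical-class taxonomy, fused per drug by a multi-width convolution.
3. **Text** — dependency-parsed description sentences encoded by a
   Bi-LSTM (`hw_t = hf_t + hb_t`) with word- and sentence-level
   attention over dependency-derived token features.

Blocks are reweighted by interactive attention
(`M = tanh(W_sw H)`, `alpha = softmax(w_w' M)`, `v_c = H alpha'`) and
concatenated into the fused drug vector; the DDI joint layer convolves
the two drugs' vectors as aligned channels and ends in
`y = softmax(W_o pr + b_o)`.

Everything runs on a built-in synthetic knowledge base with planted
latent clusters — attribute tables, fingerprints, taxonomy, CoNLL-U
descriptions, and labeled pairs are all generated with known ground
truth, so the full pipeline is testable offline at desk scale.  See the
methods vignette (`vignettes/kmr-methods.Rmd`) for the model, its
assumptions and the design decisions.

## Worked example

```r
library(kmr)

# 1. simulate a knowledge base: 200 drugs in 8 latent mechanism clusters,
#    5% attribute noise, 2000 labeled pairs
ds <- generate(generator_config(n_drugs = 200, n_clusters = 8,
                                epsilon = 0.05, n_pairs = 2000, seed = 1),
               "data/synthetic")

# 2. hold out 20% of pairs, train the DDI classifier end-to-end
sp  <- split_pairs(ds$pairs, 0.2, seed = 2024)
cfg <- kmr_desk_config(epochs = 5)
res <- train_eval_ddi(ds, sp$train, sp$test, cfg, seed = 1)
res$metrics
#> <metric_report>
#>   accuracy   0.9500
#>   precision  0.9948
#>   recall     0.9091
#>   f1         0.9500
#>   auroc      0.9546
#>   aupr       0.9721
#>   n          400

# 3. similarity regression on the frozen embeddings
emb  <- drug_embeddings(res$fit$model, res$fit$inputs)
pred <- dds_fit_predict(sp$train, sp$test, emb, cfg, seed = 1)
compute_correlations(pred, sp$test$similarity)
#> $pearson
#> [1] 0.9746357
#> $spearman
#> [1] 0.8222381
```

Held-out accuracy of 0.95 against a 0.5 chance rate means the model
recovered the planted interaction rule (shared targets + shared
mechanism cluster) essentially up to the generator's label noise; the
Spearman correlation of 0.82 means the forest head reconstructed the
planted taxonomy kinship underlying the similarity scores up to their
Gaussian noise.

A thin command-line wrapper ships at `inst/cli/kmr.R`
(`simulate`, `encode`, `train-ddi`, `dds`, `sweep`, `ablate`).

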