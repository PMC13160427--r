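# scdisent

Semi-supervised disentangled representation learning for single-cell
RNA-seq, for analysts who have a large expression matrix, a handful of
annotated cells, and several known sources of variation — technical batch,
experimental condition, cell type — that they want separated into
interpretable latent blocks instead of mixed into one embedding.

## The model

Each cell's expression vector *x* is modeled as generated from *k*
categorical factors plus a residual:

    x = G(f¹, …, fᵏ, r)

One classifier encoder per factor maps *x* to a distribution over that
factor's categories; a residual encoder produces *r*. Training minimizes

    L = L_cls + λ₁·L_ent + λ₂·L_res + λ₃·L_rec

* **L_cls** — cross-entropy of each factor prediction against the true
  label, on the small labeled subset only;
* **L_ent** — Shannon entropy of the predictions on unlabeled cells,
  pushing them toward confident, near-one-hot distributions;
* **L_res** — squared ℓ2 norm of the residual, keeping it compact so named
  factors are not under-used;
* **L_rec** — reconstruction error of a decoder that consumes the
  concatenated factor codes and the noise-injected residual
  (r′ = r + ε, ε ~ N(0, I)); mean squared error on log-normalized data or a
  negative binomial likelihood on raw counts.

Factor codes entering the decoder are probability-weighted sums of learned
per-category embedding rows; cells with a known label use the embedding row
of that label directly. Each factor therefore owns a contiguous block of
latent columns, which is what makes the latent space readable: batch lives
in its two columns, cell type in its eight, and so on.

The package also ships a factorial synthetic scRNA-seq generator with
ground-truth labels (2 batches × 2 + 2 conditions × 16 cell types, one rare
population) and a disentanglement evaluation suite: Spearman
factor-correlation matrices, MIG, SAP, DCI, Hungarian block alignment,
macro-F1 and ARI.

## Worked example

```r
library(scdisent)

sim    <- simulate_dataset(tiny_sim_config())   # 2000 cells, 200 genes, 8 cell types
ds     <- normalize_counts(sim$dataset)
masked <- mask_labels(sim$truth, fraction = 0.05, seed = 1)  # hide 95% of labels

fit  <- scd_fit(ds, masked, model_cfg = model_config(sim$spec, seed = 1),
                train_cfg = train_config(epochs = 60, seed = 1))
pred <- predict_factors(fit, ds)

unl <- masked$mask[, 1] == 0       # score only cells whose labels were hidden
f1  <- sapply(seq_along(sim$spec$factors), function(j)
  macro_f1(sim$truth$labels[unl, j], pred$labels[unl, j]))
```

With 5% labeled cells the held-out macro-F1 per factor is

```
     batch condition1 condition2  cell_type
     0.997      0.989      0.977      1.000
```

and the latent evaluation

```r
lat    <- extract_latent(fit, ds)
report <- evaluate_latent(lat$latent, lat$column_map, sim$truth, seed = 1)
print(round(report$block_scores, 2))
```

shows each factor's correlations concentrated in its own code block (rows
are latent blocks, columns ground-truth factors; entries are the block's
best one-vs-rest |Spearman ρ|):

```
           batch condition1 condition2 cell_type
batch       0.87       0.06       0.04      0.08
condition1  0.04       0.87       0.02      0.06
condition2  0.02       0.05       0.86      0.06
cell_type   0.01       0.01       0.01      0.57
residual    0.29       0.31       0.20      0.42
```

The diagonal dominance is the disentanglement: off-diagonal associations
are near zero, and the Hungarian alignment of blocks to factors scores
0.79. Note that the dimension-wise gap metrics (MIG, SAP) are near zero on
these latents *by construction* — every factor spreads over a multi-column
block, so the top two dimensions for a factor are equally informative; see
the methods vignette for why the block-level scores are the meaningful ones
here.

A command-line front end covers the same pipeline
(`exec/scdisent simulate | train | evaluate | benchmark`), writing a
manifest with seeds and checksums into every output directory.

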