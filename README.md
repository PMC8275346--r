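# invatac — invariant latent representations for single-cell ATAC-seq

Single-cell ATAC-seq measures chromatin accessibility one cell at a time,
but the resulting binary cell-by-bin matrices are dominated by technical
variation: per-cell sequencing depth spans orders of magnitude, and samples
from different batches carry systematic signatures. Embeddings that ignore
this organize cells by depth and batch instead of biology — clusters smear
along depth gradients, batches refuse to mix, rare cell types vanish.

`invatac` learns a low-dimensional representation `z` of each cell that
captures intrinsic chromatin state and is statistically independent of the
observed confounders `c` (one-hot batch ⊕ standardized log depth). The model
is a conditional variational autoencoder — encoder `q(z|x)`, decoder
`p(x|z,c)` with symmetric 1000-100-d fully connected networks — trained by
minimizing

```
L = E[ D_KL(q(z|x) ‖ N(0,I)) + λ·D_KL(q(z|x) ‖ q(z)) ]
    − (1+λ)·E[ log p(x|z,c) ]
```

The middle term upper-bounds the mutual information I(z, c) and is
approximated on each minibatch by closed-form pairwise KL divergences
between per-cell diagonal-Gaussian posteriors. The reconstruction term is a
binary cross-entropy with weight ω (the empirical 0/1 ratio) on open
entries. Training uses deterministic warmup plus cyclical KL annealing and
Adam with weight decay, implemented directly over BLAS with small C++
kernels — a 2000-cell desk run trains in about two minutes on one core.

Around the model, the package provides the full workflow:

* **Simulation** — `sim_preset()` / `simulate_experiment()`: read-level
  simulator with planted cell types, log-normal depths, batch-specific
  signal-to-noise, rare types and ground-truth bulk profiles.
* **Preprocessing** — `binarize()`, `filter_bins()` (keep bins open in
  1–90% of cells), `qc_cells()`, `build_confounders()`.
* **Representation** — `embed()` (posterior means), `knn_graph()`,
  `louvain_cluster()`.
* **Imputation** — `impute()`: decode each cell's latent mean with
  confounders pinned (mean depth, one reference batch) for a denoised,
  confounder-free accessibility landscape.
* **Evaluation** — `dice_coefficient()` against bulk truth,
  `estimate_mi()` / `mi_profile()` (Kraskov/Ross k-NN mutual information),
  `cluster_agreement()` (ARI/NMI).
* **CLI** — `inst/cli/invatac.R` with subcommands `simulate`, `train`,
  `embed`, `cluster`, `impute`, `evaluate`, `sweep-lambda`.

## Worked example

A two-batch experiment with mismatched rare cell types — one shallow sample
(median 625 fragments/cell at desk scale) and one deep sample (1250), with
different signal-to-noise ratios — is exactly the setting where naive
embeddings split by batch:

```r
library(invatac)

cfg  <- sim_preset("sim3", cells = 2000, genome_scale = 0.25, seed = 11)
ds   <- simulate_experiment(cfg)          # counts + ground truth
fb   <- filter_bins(binarize(ds$matrix))  # ~2000 informative bins survive
conf <- build_confounders(fb$matrix$depths, fb$matrix$batch_ids)

model <- train_model(fb$matrix, conf,
                     train_config(lambda_mi = 1, epochs = 80, seed = 1))
emb   <- embed(model, fb$matrix)          # 2000 x 10 latent means

# invariance: mutual information between latents and confounders
mi_profile(emb, factor(fb$matrix$batch_ids))
#> mi_estimate: mean 0.0109 nats over 10 dimension(s) (k = 3, 3 negative value(s) clamped)
mi_profile(emb, conf$depth_norm)
#> mi_estimate: mean 0.0285 nats over 10 dimension(s) (k = 3)

# clustering recovers the 6 planted types, including both 1%-rare types
cl <- louvain_cluster(knn_graph(emb, k = 16), resolution = 0.5, seed = 1)
cluster_agreement(cl$labels, ds$labels)
#>  ari  nmi
#>    1    1

# confounder-free imputation beats the raw profiles against bulk truth
imp  <- impute(model, fb$matrix)   # depth fixed at mean, one reference batch
bulk <- as.matrix(ds$bulk_profiles[, fb$kept])
ti   <- match(ds$labels, rownames(bulk))
mean(sapply(seq_len(nrow(imp)), function(i)
  dice_coefficient(bulk[ti[i], ], imp[i, ])))
#> [1] 0.885   # raw binarized input scores 0.800
```

A batch MI of ~0.01 nats means the latents carry essentially no batch
information (averaging ten clamped near-zero k-NN estimates floors out
around 0.003–0.005 even under perfect independence), while every planted
cell type — including the batch-exclusive rare ones — forms its own
cluster. Invariance converges more slowly than clustering: training
integration runs to 200 epochs (the protocol used by the acceptance
script; see the vignette) drives the batch MI down to that floor
(~0.005–0.006) and the depth MI below 0.005.

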