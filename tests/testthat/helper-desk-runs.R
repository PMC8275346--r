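# Desk-scale end-to-end runs shared by the acceptance tests: 2000 cells,
# genome and depth jointly scaled to 1/4 (per-bin read rates as at full
# scale), d = 10. Single-sample runs train for 80 epochs; the two-batch
# integration runs train to MI convergence (200 epochs; see the vignette).
# Each run is trained at most once per test session and cached.

DESK_CELLS <- 2000L
DESK_GENOME_SCALE <- 0.25
DESK_EPOCHS <- c(sim1 = 80L, sim2 = 80L, sim3 = 200L)
DESK_SEED <- 11L

desk_runs <- local({
  cache <- list()
  function(preset, lambda = 1) {
    key <- paste0(preset, "_l", lambda)
    if (is.null(cache[[key]])) {
      cfg <- sim_preset(preset, cells = DESK_CELLS,
                        genome_scale = DESK_GENOME_SCALE, seed = DESK_SEED)
      ds <- simulate_experiment(cfg)
      fb <- filter_bins(binarize(ds$matrix))
      conf <- build_confounders(fb$matrix$depths, fb$matrix$batch_ids)
      tc <- train_config(d = 10L, lambda_mi = lambda,
                         epochs = DESK_EPOCHS[[preset]], seed = 1L)
      model <- train_model(fb$matrix, conf, tc)
      cache[[key]] <<- list(ds = ds, fb = fb, conf = conf, model = model,
                            emb = embed(model, fb$matrix))
    }
    cache[[key]]
  }
})

# best agreement over a small resolution grid (one planted partition expected)
best_louvain_agreement <- function(emb, truth, resolutions = c(0.2, 0.5, 1)) {
  g <- knn_graph(emb, k = 16)
  best <- NULL
  for (res in resolutions) {
    cl <- louvain_cluster(g, resolution = res, seed = 1)
    ag <- cluster_agreement(cl$labels, truth)
    if (is.null(best) || ag["ari"] > best$ari)
      best <- list(ari = unname(ag["ari"]), nmi = unname(ag["nmi"]), cl = cl)
  }
  best
}

# TRUE when every cell of `type` sits in one cluster containing nothing else
type_isolated <- function(labels, truth, type) {
  in_type <- truth == type
  cl <- unique(labels[in_type])
  length(cl) == 1 && all(truth[labels == cl] == type)
}

mean_dice_vs_bulk <- function(run, profiles) {
  bulk_kept <- as.matrix(run$ds$bulk_profiles[, run$fb$kept, drop = FALSE])
  ti <- match(run$ds$labels, rownames(bulk_kept))
  vapply(seq_len(nrow(profiles)), function(i)
    dice_coefficient(bulk_kept[ti[i], ], profiles[i, ]), numeric(1))
}
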