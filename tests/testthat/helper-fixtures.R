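# Shared fixtures. Small objects are built eagerly; the desk-scale trained
# models used by the end-to-end tests are built lazily and cached for the
# whole test run, since several test files interrogate the same runs.

make_toy_matrix <- function(n_cells = 20, n_bins = 12, seed = 1,
                            batches = rep("batch1", n_cells)) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_bins, 0.8), n_cells, n_bins)
  cell_matrix(m, batch_ids = batches)
}

# tiny trained model for interface-level tests (seconds, not minutes)
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_preset("sim1", cells = 250, genome_scale = 0.05, seed = 5)
      ds <- simulate_experiment(cfg)
      fb <- filter_bins(binarize(ds$matrix))
      conf <- build_confounders(fb$matrix$depths, fb$matrix$batch_ids)
      tc <- train_config(d = 4, hidden_sizes = c(48L, 24L), epochs = 10,
                         minibatch_size = 64, seed = 2)
      cache <<- list(ds = ds, fb = fb, conf = conf,
                     model = train_model(fb$matrix, conf, tc))
    }
    cache
  }
})

# tiny two-batch model (for imputation batch-fixing tests)
tiny_trained_2batch <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_preset("sim3", cells = 300, genome_scale = 0.05, seed = 6)
      ds <- simulate_experiment(cfg)
      fb <- filter_bins(binarize(ds$matrix))
      conf <- build_confounders(fb$matrix$depths, fb$matrix$batch_ids)
      tc <- train_config(d = 4, hidden_sizes = c(48L, 24L), epochs = 10,
                         minibatch_size = 64, seed = 2)
      cache <<- list(ds = ds, fb = fb, conf = conf,
                     model = train_model(fb$matrix, conf, tc))
    }
    cache
  }
})

# brute-force scalar oracle for the weighted reconstruction loss
loop_wbce <- function(x, xh, omega, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      p <- min(max(xh[i, j], eps), 1 - eps)
      tot <- tot + omega * x[i, j] * log(p) + (1 - x[i, j]) * log(1 - p)
    }
  }
  -tot / nrow(x)
}

# numerical-integration oracle for the 1-D Gaussian KL divergence
quadrature_kl_1d <- function(mu1, lv1, mu2, lv2) {
  s1 <- exp(lv1 / 2); s2 <- exp(lv2 / 2)
  f <- function(x) {
    p <- stats::dnorm(x, mu1, s1)
    ifelse(p == 0, 0, p * (stats::dnorm(x, mu1, s1, log = TRUE) -
                             stats::dnorm(x, mu2, s2, log = TRUE)))
  }
  stats::integrate(f, mu1 - 12 * s1, mu1 + 12 * s1, rel.tol = 1e-9)$value
}

# double-loop oracle for the pairwise KL penalty (mean over ordered pairs)
loop_pairwise_kl <- function(mu, lv) {
  B <- nrow(mu); tot <- 0
  for (i in seq_len(B)) {
    for (j in seq_len(B)) {
      if (i == j) next
      tot <- tot + sum(0.5 * (exp(lv[i, ] - lv[j, ]) +
                                (mu[j, ] - mu[i, ])^2 / exp(lv[j, ]) -
                                1 + lv[j, ] - lv[i, ]))
    }
  }
  tot / (B * (B - 1))
}
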