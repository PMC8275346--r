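# The invariant conditional VAE: a 1000-100-d encoder with Gaussian mean /
# log-variance heads, a symmetric conditional decoder taking [z, c] with a
# sigmoid output layer, hand-written backpropagation, and Adam with weight
# decay. Matrix algebra throughout (one BLAS gemm per layer), so the training
# loop stays fast on a single CPU at the problem sizes the package targets.

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(a) 1 / (1 + exp(-a))
softplus <- function(a) log1p(exp(-abs(a))) + pmax(a, 0)

LOGVAR_CLAMP <- 10 # |log-variance| bound; keeps exp() finite, gradient masked

#' Training configuration
#'
#' @param d latent dimension (default 10).
#' @param hidden_sizes encoder hidden widths, input to latent (default
#'   `c(1000, 100)`; the decoder mirrors them).
#' @param lambda_mi invariance weight `lambda >= 0` (default 1).
#' @param omega reconstruction weight; `NULL` (default) computes it from the
#'   empirical 0/1 ratio of the training matrix.
#' @param learning_rate Adam step size (default 1e-3).
#' @param weight_decay L2 weight decay on weight matrices (default 5e-4).
#' @param epochs training epochs (default 400).
#' @param minibatch_size cells per minibatch (>= 2; default 128).
#' @param warmup_epochs epochs with `beta = 0`; default 10% of `epochs`.
#' @param n_anneal_cycles annealing cycles after warmup (default 4).
#' @param pairwise_normalize normalization of the pairwise-KL term during
#'   training (see [pairwise_kl_penalty()]). Default `"pairs"` (mean over
#'   ordered pairs), which keeps the term's magnitude — and hence the meaning
#'   of `lambda` — independent of the minibatch size.
#' @param val_fraction held-out fraction for validation logging (default 0.1).
#' @param seed master seed for initialization, shuffling and sampling.
#' @param verbose print a progress line every 10 epochs.
#' @return object of class `train_config`.
#' @export
train_config <- function(d = 10L, hidden_sizes = c(1000L, 100L),
                         lambda_mi = 1, omega = NULL, learning_rate = 1e-3,
                         weight_decay = 5e-4, epochs = 400L,
                         minibatch_size = 128L, warmup_epochs = NULL,
                         n_anneal_cycles = 4L, pairwise_normalize = "pairs",
                         val_fraction = 0.1, seed = 1L, verbose = FALSE) {
  stop_if_not(d >= 1, "latent dimension d must be >= 1")
  stop_if_not(lambda_mi >= 0, "lambda_mi must be >= 0")
  stop_if_not(is.null(omega) || omega >= 1, "omega must be >= 1")
  stop_if_not(minibatch_size >= 2,
              "minibatch_size must be >= 2 (the pairwise term needs pairs)")
  warmup_epochs <- warmup_epochs %||% max(1L, as.integer(round(0.1 * epochs)))
  stop_if_not(warmup_epochs < epochs, "warmup_epochs must be < epochs")
  structure(list(d = as.integer(d), hidden_sizes = as.integer(hidden_sizes),
                 lambda_mi = lambda_mi, omega = omega,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 warmup_epochs = as.integer(warmup_epochs),
                 n_anneal_cycles = as.integer(n_anneal_cycles),
                 pairwise_normalize = pairwise_normalize,
                 val_fraction = val_fraction, seed = as.integer(seed),
                 verbose = verbose),
            class = "train_config")
}

dense_layer <- function(fan_in, fan_out, w_sd) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, 0, w_sd), fan_in, fan_out),
       b = rep(0, fan_out))
}

init_params <- function(n_input, n_conf, config) {
  with_seed(child_seed(config$seed, 1L), {
    h <- config$hidden_sizes; d <- config$d
    enc_dims <- c(n_input, h)
    enc <- lapply(seq_len(length(enc_dims) - 1L), function(i)
      dense_layer(enc_dims[i], enc_dims[i + 1L], sqrt(2 / enc_dims[i])))
    top <- h[length(h)]
    dec_dims <- c(d + n_conf, rev(h), n_input)
    dec <- lapply(seq_len(length(dec_dims) - 1L), function(i)
      dense_layer(dec_dims[i], dec_dims[i + 1L], sqrt(2 / dec_dims[i])))
    structure(list(enc = enc,
                   mu_head = dense_layer(top, d, sqrt(1 / top)),
                   lv_head = dense_layer(top, d, 0.01),
                   dec = dec,
                   n_input = n_input, n_conf = as.integer(n_conf),
                   d = d),
              class = "invae_params")
  })
}

# Forward through the encoder stack; returns hidden activations (for
# backprop) plus the clamped posterior parameters. The bias-add + ReLU is a
# fused in-place kernel applied to the fresh matmul result.
forward_encoder <- function(params, X) {
  stop_if_not(ncol(X) == params$n_input,
              "input has ", ncol(X), " bins but the model expects ",
              params$n_input)
  hs <- vector("list", length(params$enc))
  A <- X
  for (i in seq_along(params$enc)) {
    A <- cpp_bias_relu(A %*% params$enc[[i]]$W, params$enc[[i]]$b, TRUE)
    hs[[i]] <- A
  }
  mu <- cpp_bias_relu(A %*% params$mu_head$W, params$mu_head$b, FALSE)
  lv_raw <- cpp_bias_relu(A %*% params$lv_head$W, params$lv_head$b, FALSE)
  lv <- pmin(pmax(lv_raw, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(hidden = hs, mu = mu, lv = lv, lv_raw = lv_raw)
}

forward_decoder <- function(params, z, C) {
  stop_if_not(ncol(z) == params$d, "z has wrong latent dimension")
  stop_if_not(ncol(C) == params$n_conf,
              "confounder vector has ", ncol(C), " columns but the model expects ",
              params$n_conf)
  A <- cbind(z, C)
  gs <- vector("list", length(params$dec) - 1L)
  for (i in seq_len(length(params$dec) - 1L)) {
    A <- cpp_bias_relu(A %*% params$dec[[i]]$W, params$dec[[i]]$b, TRUE)
    gs[[i]] <- A
  }
  last <- params$dec[[length(params$dec)]]
  logits <- cpp_bias_relu(A %*% last$W, last$b, FALSE)
  list(hidden = gs, logits = logits, prob = sigmoid(logits))
}

#' Draw a reparameterized latent sample
#'
#' `z = mean + exp(log_var / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param posterior a [gaussian_posterior()].
#' @param seed integer seed for the draw.
#' @return matrix of samples, one row per cell.
#' @export
sample_latent <- function(posterior, seed = 1L) {
  stopifnot(inherits(posterior, "gaussian_posterior"))
  m <- posterior$mean
  eps <- with_seed(seed, matrix(stats::rnorm(length(m)), nrow(m), ncol(m)))
  m + exp(posterior$log_var / 2) * eps
}

# One gradient evaluation on a dense minibatch. Returns the analytic
# gradients of the full objective plus the loss components. The decoder
# forward is inlined so the weighted-BCE value and logit gradient come out
# of one fused pass over the logits.
invae_step <- function(params, Xb, Cb, omega, lambda, beta, eps,
                       pairwise_normalize = "pairs") {
  B <- nrow(Xb)
  fe <- forward_encoder(params, Xb)
  mu <- fe$mu; lv <- fe$lv
  z <- mu + exp(lv / 2) * eps

  dec_in <- cbind(z, Cb)
  gs <- vector("list", length(params$dec) - 1L)
  A <- dec_in
  for (i in seq_len(length(params$dec) - 1L)) {
    A <- cpp_bias_relu(A %*% params$dec[[i]]$W, params$dec[[i]]$b, TRUE)
    gs[[i]] <- A
  }
  nd <- length(params$dec)
  A <- cpp_bias_relu(A %*% params$dec[[nd]]$W, params$dec[[nd]]$b, FALSE)

  # A is overwritten in place with the scaled dL/dlogits
  recon <- cpp_wbce_grad(A, Xb, omega, (1 + lambda) / B) / B
  klp <- mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
  post <- gaussian_posterior(mu, lv)
  klpair <- pairwise_kl_penalty(post, normalize = pairwise_normalize)
  total <- beta * (klp + lambda * klpair) + (1 + lambda) * recon

  grads <- list(enc = vector("list", length(params$enc)),
                dec = vector("list", length(params$dec)))

  # ---- reconstruction path (weight 1 + lambda, already folded into dA) ----
  dH <- A
  for (i in nd:1) {
    below <- if (i == 1L) dec_in else gs[[i - 1L]]
    grads$dec[[i]] <- list(W = crossprod(below, dH), b = colSums(dH))
    dH <- tcrossprod(dH, params$dec[[i]]$W)
    if (i > 1L) dH <- cpp_relu_mask(dH, gs[[i - 1L]])
  }
  dz <- dH[, seq_len(params$d), drop = FALSE]
  dmu <- dz
  dlv <- dz * eps * 0.5 * exp(lv / 2)

  # ---- KL to prior (weight beta) ----
  dmu <- dmu + (beta / B) * mu
  dlv <- dlv + (beta / (2 * B)) * (exp(lv) - 1)

  # ---- pairwise-KL penalty (weight beta * lambda), closed-form gradient ----
  if (beta * lambda > 0) {
    w <- beta * lambda * pairwise_norm_factor(pairwise_normalize, B)
    V <- exp(lv); iV <- exp(-lv)
    SiV <- colSums(iV); SV <- colSums(V)
    Sm <- colSums(mu); Sq <- colSums(mu^2); SmiV <- colSums(mu * iV)
    g_mu <- mu * rep(SiV, each = B) - rep(SmiV, each = B) +
      iV * (B * mu - rep(Sm, each = B))
    g_lv <- 0.5 * (V * rep(SiV, each = B) - iV * rep(SV, each = B) -
                     iV * (rep(Sq, each = B) - 2 * mu * rep(Sm, each = B) +
                             B * mu^2))
    dmu <- dmu + w * g_mu
    dlv <- dlv + w * g_lv
  }

  # clamp mask on the log-variance head
  dlv <- dlv * (abs(fe$lv_raw) < LOGVAR_CLAMP)

  # ---- encoder backprop ----
  hs <- fe$hidden
  top <- hs[[length(hs)]]
  grads$mu_head <- list(W = crossprod(top, dmu), b = colSums(dmu))
  grads$lv_head <- list(W = crossprod(top, dlv), b = colSums(dlv))
  dH <- cpp_relu_mask(tcrossprod(dmu, params$mu_head$W) +
                        tcrossprod(dlv, params$lv_head$W), top)
  ne <- length(params$enc)
  for (i in ne:1) {
    below <- if (i == 1L) Xb else hs[[i - 1L]]
    grads$enc[[i]] <- list(W = crossprod(below, dH), b = colSums(dH))
    if (i > 1L) {
      dH <- cpp_relu_mask(tcrossprod(dH, params$enc[[i]]$W), hs[[i - 1L]])
    }
  }

  list(grads = grads,
       components = list(total = total, recon = recon, kl_prior = klp,
                         kl_pairwise = klpair))
}

# ---- Adam with decoupled-from-biases L2 weight decay ----

adam_init <- function(params) {
  zero_like <- function(l) list(W = l$W * 0, b = l$b * 0)
  list(m = list(enc = lapply(params$enc, zero_like),
                mu_head = zero_like(params$mu_head),
                lv_head = zero_like(params$lv_head),
                dec = lapply(params$dec, zero_like)),
       v = list(enc = lapply(params$enc, zero_like),
                mu_head = zero_like(params$mu_head),
                lv_head = zero_like(params$lv_head),
                dec = lapply(params$dec, zero_like)),
       t = 0L)
}

# Fused in-place Adam: parameter and moment tensors are updated by the C++
# kernel without copies, so `params` and `state` are mutated through their
# array storage (they are only ever owned by the training loop).
adam_update <- function(params, grads, state, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  upd <- function(layer, g, m, v) {
    # L2 decay on weight matrices only, not biases
    cpp_adam_update(layer$W, g$W, m$W, v$W, lr, beta1, beta2, eps, bc1, bc2, wd)
    cpp_adam_update(layer$b, g$b, m$b, v$b, lr, beta1, beta2, eps, bc1, bc2, 0)
  }
  for (i in seq_along(params$enc))
    upd(params$enc[[i]], grads$enc[[i]], state$m$enc[[i]], state$v$enc[[i]])
  upd(params$mu_head, grads$mu_head, state$m$mu_head, state$v$mu_head)
  upd(params$lv_head, grads$lv_head, state$m$lv_head, state$v$lv_head)
  for (i in seq_along(params$dec))
    upd(params$dec[[i]], grads$dec[[i]], state$m$dec[[i]], state$v$dec[[i]])
  list(params = params, state = state)
}

#' Train the invariant conditional VAE
#'
#' Minibatch gradient optimization of the full objective (reconstruction +
#' prior KL + pairwise-KL invariance penalty) with deterministic warmup and
#' cyclical annealing of the KL block, Adam with weight decay, a held-out
#' validation split whose reconstruction log-likelihood is logged per epoch,
#' and full seed control.
#'
#' @param matrix a binarized, bin-filtered [cell_matrix()].
#' @param confounders a [build_confounders()] table aligned with `matrix`.
#' @param config a [train_config()].
#' @return object of class `invae_model`: network parameters, the config,
#'   `omega`, the batch vocabulary, depth-normalization statistics, the bin
#'   coordinates of the model's input columns, the identifier of the
#'   highest-median-depth batch (used as the fixed batch in imputation) and a
#'   per-epoch training log.
#' @export
train_model <- function(matrix, confounders, config = train_config()) {
  stopifnot(inherits(matrix, "cell_matrix"), inherits(config, "train_config"))
  stop_if_not(isTRUE(matrix$binarized), "train_model expects a binarized matrix")
  stopifnot(inherits(confounders, "confounder_table"))
  X <- matrix$counts
  C <- confounders$combined
  n <- nrow(X)
  stop_if_not(nrow(C) == n, "confounder table does not align with the matrix")
  omega <- config$omega %||% compute_omega(matrix)

  params <- init_params(ncol(X), ncol(C), config)
  state <- adam_init(params)

  n_val <- max(2L, as.integer(round(config$val_fraction * n)))
  val_idx <- with_seed(child_seed(config$seed, 2L), sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  Xval <- as.matrix(X[val_idx, , drop = FALSE])
  Cval <- C[val_idx, , drop = FALSE]

  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs) - 1L) {
    beta <- kl_weight(epoch, config$warmup_epochs, config$n_anneal_cycles,
                      config$epochs)
    ord <- with_seed(child_seed(config$seed, 1000L + epoch),
                     sample(train_idx))
    starts <- seq(1L, length(ord), by = config$minibatch_size)
    comp_sum <- c(total = 0, recon = 0, kl_prior = 0, kl_pairwise = 0)
    n_steps <- 0L
    for (s in seq_along(starts)) {
      mb <- ord[starts[s]:min(starts[s] + config$minibatch_size - 1L,
                              length(ord))]
      if (length(mb) < 2L) next
      Xb <- as.matrix(X[mb, , drop = FALSE])
      Cb <- C[mb, , drop = FALSE]
      eps <- with_seed(child_seed(config$seed, 10000L + epoch * 1000L + s),
                       matrix(stats::rnorm(length(mb) * config$d),
                              length(mb), config$d))
      st <- invae_step(params, Xb, Cb, omega, config$lambda_mi, beta, eps,
                       config$pairwise_normalize)
      comps <- unlist(st$components)
      if (!all(is.finite(comps)))
        stop("non-finite loss at epoch ", epoch, ": ",
             paste(names(comps)[!is.finite(comps)], collapse = ", "),
             call. = FALSE)
      r <- adam_update(params, st$grads, state, config$learning_rate,
                       config$weight_decay)
      params <- r$params; state <- r$state
      comp_sum <- comp_sum + comps[names(comp_sum)]
      n_steps <- n_steps + 1L
    }
    fe_val <- forward_encoder(params, Xval)
    xh_val <- forward_decoder(params, fe_val$mu, Cval)$prob
    val_loss <- weighted_reconstruction_loss(Xval, xh_val, omega)
    log_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, beta = beta, t(comp_sum / n_steps),
      val_recon = val_loss, val_ll = -val_loss)
    if (config$verbose && (epoch %% 10L == 0L || epoch == config$epochs - 1L))
      message(sprintf("epoch %3d beta %.2f loss %.2f recon %.2f klp %.3f pair %.3f val %.2f",
                      epoch, beta, comp_sum[["total"]] / n_steps,
                      comp_sum[["recon"]] / n_steps,
                      comp_sum[["kl_prior"]] / n_steps,
                      comp_sum[["kl_pairwise"]] / n_steps, val_loss))
  }

  med_by_batch <- tapply(matrix$depths, matrix$batch_ids, stats::median)
  structure(list(params = params, config = config, omega = omega,
                 batch_levels = confounders$batch_levels,
                 depth_log_mean = confounders$depth_log_mean,
                 depth_log_sd = confounders$depth_log_sd,
                 bin_coords = matrix$bin_coords,
                 best_batch = names(which.max(med_by_batch)),
                 log = do.call(rbind, log_rows)),
            class = "invae_model")
}

#' @export
print.invae_model <- function(x, ...) {
  cat(sprintf(paste0("invae_model: %d input bins -> d = %d, lambda = %g, ",
                     "batches [%s], %d epochs\n"),
              x$params$n_input, x$params$d, x$config$lambda_mi,
              paste(x$batch_levels, collapse = ", "), x$config$epochs))
  invisible(x)
}

#' Encode cells into posterior parameters
#'
#' Deterministic map from binarized profiles to the per-cell diagonal-Gaussian
#' posterior of the latent representation.
#'
#' @param model a trained `invae_model` (or bare `invae_params`).
#' @param x a [cell_matrix()] preprocessed with the model's bin map, or a
#'   matrix with matching columns.
#' @param chunk cells per forward chunk (memory control).
#' @return a [gaussian_posterior()] with one row per cell.
#' @export
encode <- function(model, x, chunk = 1024L) {
  params <- if (inherits(model, "invae_model")) model$params else model
  M <- if (inherits(x, "cell_matrix")) x$counts else x
  if (ncol(M) != params$n_input)
    stop("dimension mismatch: input has ", ncol(M),
         " bins but the model was trained on ", params$n_input, call. = FALSE)
  n <- nrow(M)
  mu <- matrix(0, n, params$d); lv <- matrix(0, n, params$d)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    fe <- forward_encoder(params, as.matrix(M[idx, , drop = FALSE]))
    mu[idx, ] <- fe$mu; lv[idx, ] <- fe$lv
  }
  if (inherits(x, "cell_matrix")) rownames(mu) <- rownames(lv) <- x$cell_ids
  gaussian_posterior(mu, lv)
}

#' Decode latent representations into accessibility probabilities
#'
#' @param model a trained `invae_model` (or bare `invae_params`).
#' @param z latent matrix (cells x d).
#' @param c confounder matrix aligned with `z`.
#' @return matrix of per-bin probabilities in (0, 1).
#' @export
decode <- function(model, z, c) {
  params <- if (inherits(model, "invae_model")) model$params else model
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (is.null(dim(c))) c <- matrix(c, nrow = 1)
  stop_if_not(nrow(z) == nrow(c), "z and c must align")
  forward_decoder(params, z, c)$prob
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the parameters, the training
#' configuration, the bin coordinate map, the batch vocabulary and the
#' depth-normalization statistics, so that inference reproduces training-time
#' preprocessing exactly.
#'
#' @param model an `invae_model`.
#' @param path file path for the checkpoint.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `invae_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "invae_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "invae_model"))
    stop("checkpoint does not contain an invae_model", call. = FALSE)
  model
}
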