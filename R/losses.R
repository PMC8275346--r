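# Loss components of the invariant conditional VAE. The training objective is
#
#   L = E_x[ D_KL(q(z|x) || p(z)) + lambda * D_KL(q(z|x) || q(z)) ]
#       - (1 + lambda) * E_{x,c}[ E_{z~q(z|x)} log p(x|z,c) ]
#
# where the marginal-KL term upper-bounds the mutual information I(z, c) (up
# to a constant) and is approximated on each minibatch by pairwise KL
# divergences between the per-cell diagonal-Gaussian posteriors.

#' Diagonal-Gaussian posterior parameters
#'
#' Per-cell mean and log-variance of the encoder posterior `q(z|x)`. One row
#' per cell; a plain vector is treated as a single cell.
#'
#' @param mean numeric vector or cells x d matrix.
#' @param log_var numeric vector or matrix of matching shape.
#' @return object of class `gaussian_posterior` with matrix fields `mean` and
#'   `log_var`.
#' @export
gaussian_posterior <- function(mean, log_var) {
  if (is.null(dim(mean))) mean <- matrix(mean, nrow = 1)
  if (is.null(dim(log_var))) log_var <- matrix(log_var, nrow = 1)
  stop_if_not(all(dim(mean) == dim(log_var)),
              "mean and log_var must have identical shapes")
  stop_if_not(all(is.finite(mean)) && all(is.finite(log_var)),
              "posterior parameters must be finite")
  structure(list(mean = mean, log_var = log_var), class = "gaussian_posterior")
}

#' @export
print.gaussian_posterior <- function(x, ...) {
  cat(sprintf("gaussian_posterior: %d cell(s), d = %d\n",
              nrow(x$mean), ncol(x$mean)))
  invisible(x)
}

#' Reconstruction weight from the empirical 0/1 ratio
#'
#' The positive weight placed on open (1) entries in the weighted binary
#' cross-entropy, `omega = #zeros / #ones`, clamped to at least 1. Computed as
#' one global scalar on the binarized (and typically bin-filtered) matrix.
#'
#' @param matrix a binarized [cell_matrix()] or 0/1 matrix.
#' @return positive scalar `omega >= 1`.
#' @export
compute_omega <- function(matrix) {
  m <- if (inherits(matrix, "cell_matrix")) matrix$counts else matrix
  total <- as.double(nrow(m)) * as.double(ncol(m))
  ones <- if (methods::is(m, "sparseMatrix")) sum(m@x != 0) else sum(m != 0)
  if (ones == 0) stop("all-zero matrix: omega undefined", call. = FALSE)
  max(1, (total - ones) / ones)
}

#' Weighted binary cross-entropy reconstruction loss
#'
#' `-sum_j [ omega * x_j * ln(xhat_j) + (1 - x_j) * ln(1 - xhat_j) ]`, summed
#' over bins and averaged over cells. Predicted probabilities are clamped to
#' `[eps, 1 - eps]` inside the logarithms.
#'
#' @param x binary matrix (cells x bins) or vector.
#' @param x_hat predicted probabilities of matching shape.
#' @param omega positive weight on open entries (>= 1).
#' @param eps clamp width (default 1e-7).
#' @return non-negative scalar.
#' @export
weighted_reconstruction_loss <- function(x, x_hat, omega, eps = 1e-7) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(x_hat))) x_hat <- matrix(x_hat, nrow = 1)
  stop_if_not(all(dim(x) == dim(x_hat)), "x and x_hat must have equal shapes")
  stop_if_not(omega >= 1, "omega must be >= 1")
  xh <- pmin(pmax(x_hat, eps), 1 - eps)
  ll <- omega * x * log(xh) + (1 - x) * log1p(-xh)
  -mean(rowSums(ll))
}

#' Closed-form KL divergence between diagonal Gaussians
#'
#' `KL(p || q) = 1/2 * sum_k [ exp(lv_p - lv_q) + (mu_q - mu_p)^2 / exp(lv_q)
#' - 1 + lv_q - lv_p ]`. For multi-row posteriors the divergence is computed
#' row by row.
#'
#' @param p,q [gaussian_posterior()] objects of equal shape.
#' @return numeric vector of per-row divergences (scalar for one row).
#' @export
gaussian_kl <- function(p, q) {
  stopifnot(inherits(p, "gaussian_posterior"), inherits(q, "gaussian_posterior"))
  stop_if_not(all(dim(p$mean) == dim(q$mean)), "posterior dimensions differ")
  dlv <- p$log_var - q$log_var
  out <- 0.5 * rowSums(exp(dlv) + (q$mean - p$mean)^2 / exp(q$log_var) - 1 - dlv)
  if (length(out) == 1L) out <- unname(out)
  out
}

#' KL divergence of posteriors to the standard-normal prior
#'
#' `KL(q(z|x) || N(0, I))`, averaged over the cells (rows) of the posterior.
#'
#' @param posterior a [gaussian_posterior()].
#' @return non-negative scalar.
#' @export
kl_to_prior <- function(posterior) {
  stopifnot(inherits(posterior, "gaussian_posterior"))
  m <- posterior$mean; lv <- posterior$log_var
  mean(0.5 * rowSums(m^2 + exp(lv) - 1 - lv))
}

#' Pairwise-KL approximation of the marginal-KL (mutual-information) penalty
#'
#' Approximates `E_x[ D_KL(q(z|x) || q(z)) ]` on a minibatch by KL divergences
#' between all ordered pairs of per-cell posteriors, computed with the closed
#' form in a fully vectorized way. By default the sum is divided by the number
#' of ordered pairs `B(B-1)` so the term's magnitude — and hence a given
#' `lambda` — transfers across minibatch sizes; `normalize = FALSE` yields
#' the raw sum.
#'
#' Three normalizations are offered: `"pairs"` (mean over the `B(B-1)`
#' ordered pairs — magnitude independent of minibatch size), `"cells"` (mean
#' over cells of each cell's summed divergence to its `B-1` batch partners —
#' the printed objective, and the scale at which `lambda = 1` produces strong
#' invariance; the training default), and `"sum"` (raw ordered-pair sum).
#'
#' @param posteriors a [gaussian_posterior()] with at least two rows, or a
#'   list of single-cell posteriors.
#' @param normalize `"pairs"` (default), `"cells"` or `"sum"`; `TRUE`/`FALSE`
#'   are accepted as aliases for `"pairs"`/`"sum"`.
#' @return non-negative scalar.
#' @export
pairwise_kl_penalty <- function(posteriors, normalize = "pairs") {
  if (is.list(posteriors) && !inherits(posteriors, "gaussian_posterior")) {
    posteriors <- gaussian_posterior(
      do.call(rbind, lapply(posteriors, function(p) p$mean)),
      do.call(rbind, lapply(posteriors, function(p) p$log_var)))
  }
  stopifnot(inherits(posteriors, "gaussian_posterior"))
  m <- posteriors$mean; lv <- posteriors$log_var
  B <- nrow(m); d <- ncol(m)
  if (B < 2) stop("pairwise KL penalty needs a minibatch of >= 2 cells",
                  call. = FALSE)
  V <- exp(lv); iV <- exp(-lv)
  SV <- colSums(V); SiV <- colSums(iV)
  Sm <- colSums(m); Sq <- colSums(m^2); SmiV <- colSums(m * iV)
  Sq_iV <- colSums(m^2 * iV)
  # column-wise sums give the pair sums in O(B d); the diagonal (i = j) adds
  # exactly d to each exp-term row and zero elsewhere, and the log-var terms
  # cancel over ordered pairs
  t_exp <- sum(SV * SiV) - B * d
  t_mu <- sum(Sq * SiV) - 2 * sum(Sm * SmiV) + B * sum(Sq_iV)
  total <- 0.5 * (t_exp + t_mu - d * B * (B - 1))
  total * pairwise_norm_factor(normalize, B)
}

pairwise_norm_factor <- function(normalize, B) {
  if (isTRUE(normalize)) normalize <- "pairs"
  if (isFALSE(normalize)) normalize <- "sum"
  switch(match.arg(normalize, c("pairs", "cells", "sum")),
         pairs = 1 / (B * (B - 1)),
         cells = 1 / B,
         sum = 1)
}

#' Annealing weight on the KL block
#'
#' Deterministic warmup followed by cyclical annealing: `beta = 0` for the
#' first `warmup_epochs` epochs; the remaining epochs are split into
#' `n_cycles` equal cycles, each ramping `beta` linearly from 0 to 1 over its
#' first half and holding `beta = 1` over its second half. Counteracts
#' posterior collapse ("KL vanishing") early in training.
#'
#' @param epoch 0-based epoch index.
#' @param warmup_epochs number of warmup epochs with `beta = 0`.
#' @param n_cycles number of annealing cycles (>= 1).
#' @param total_epochs total number of training epochs.
#' @return `beta` in `[0, 1]`.
#' @export
kl_weight <- function(epoch, warmup_epochs, n_cycles, total_epochs) {
  stop_if_not(total_epochs >= 1, "total_epochs must be >= 1")
  stop_if_not(epoch >= 0 && epoch < total_epochs,
              "epoch must satisfy 0 <= epoch < total_epochs")
  stop_if_not(warmup_epochs >= 0 && warmup_epochs < total_epochs,
              "warmup_epochs must satisfy 0 <= warmup < total_epochs")
  stop_if_not(n_cycles >= 1, "n_cycles must be >= 1")
  if (epoch < warmup_epochs) return(0)
  cycle_len <- (total_epochs - warmup_epochs) / n_cycles
  frac <- ((epoch - warmup_epochs) %% cycle_len) / cycle_len
  min(1, 2 * frac)
}

#' Full training loss on one minibatch
#'
#' `beta * [ KL(q || prior) + lambda * pairwise-KL penalty ] +
#' (1 + lambda) * weighted reconstruction loss`, with one Monte-Carlo sample
#' of `z` per cell. `beta = 1` recovers the exact objective; `beta = 0`
#' isolates the reconstruction term.
#'
#' @param x binary minibatch matrix (>= 2 cells x bins).
#' @param c aligned confounder matrix.
#' @param params model parameters (an `invae_model` or its `$params`).
#' @param omega reconstruction weight.
#' @param lambda invariance weight (>= 0).
#' @param beta annealing weight in `[0, 1]`.
#' @param seed seed for the latent sample.
#' @param pairwise_normalize normalization passed to [pairwise_kl_penalty()]
#'   (default `"pairs"`).
#' @return list with `total` and components `recon`, `kl_prior`,
#'   `kl_pairwise`, plus the weights used.
#' @export
total_loss <- function(x, c, params, omega, lambda = 1, beta = 1, seed = 1L,
                       pairwise_normalize = "pairs") {
  if (inherits(params, "invae_model")) params <- params$params
  stop_if_not(nrow(x) >= 2, "total_loss needs a minibatch of >= 2 cells")
  stop_if_not(nrow(x) == nrow(c), "x and c must have aligned rows")
  stop_if_not(lambda >= 0, "lambda must be >= 0")
  fe <- forward_encoder(params, as.matrix(x))
  post <- gaussian_posterior(fe$mu, fe$lv)
  z <- sample_latent(post, seed = seed)
  xh <- forward_decoder(params, z, as.matrix(c))$prob
  recon <- weighted_reconstruction_loss(as.matrix(x), xh, omega)
  klp <- kl_to_prior(post)
  klpair <- pairwise_kl_penalty(post, normalize = pairwise_normalize)
  list(total = beta * (klp + lambda * klpair) + (1 + lambda) * recon,
       recon = recon, kl_prior = klp, kl_pairwise = klpair,
       lambda = lambda, beta = beta)
}
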