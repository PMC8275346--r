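test_that("omega reflects the 0/1 imbalance with a floor at 1", {
  m <- matrix(0, 10, 10); m[1, 1:10] <- 1
  expect_equal(compute_omega(binarize(cell_matrix(m))), 9)
  half <- matrix(rep(c(0, 1), 50), 10, 10)
  expect_equal(compute_omega(binarize(cell_matrix(half))), 1)
  toy <- matrix(0, 4, 5); toy[c(2, 11)] <- 1 # 4x5, 2 ones -> 18/2
  expect_equal(compute_omega(binarize(cell_matrix(toy))), 9)
  expect_error(compute_omega(matrix(0, 3, 3)), "all-zero")
})

test_that("weighted reconstruction loss matches its closed form and oracle", {
  expect_equal(weighted_reconstruction_loss(1, 0.5, omega = 2), -2 * log(0.5))
  x <- c(1, 0, 1)
  expect_lt(weighted_reconstruction_loss(x, c(1 - 1e-9, 1e-9, 1 - 1e-9), 3), 1e-5)
  set.seed(11)
  xr <- matrix(rbinom(35, 1, 0.4), 5, 7)
  xh <- matrix(runif(35), 5, 7)
  expect_equal(weighted_reconstruction_loss(xr, xh, 2.5),
               loop_wbce(xr, xh, 2.5), tolerance = 1e-12)
})

test_that("gaussian KL matches closed-form special cases and quadrature", {
  p <- gaussian_posterior(c(0, 1), c(0, 0))
  expect_equal(gaussian_kl(p, p), 0)
  expect_equal(gaussian_kl(gaussian_posterior(0, 0), gaussian_posterior(1, 0)),
               0.5)
  set.seed(12)
  for (i in 1:20) {
    mu <- rnorm(2); lv <- rnorm(2, 0, 0.7)
    p1 <- gaussian_posterior(mu[1], lv[1]); p2 <- gaussian_posterior(mu[2], lv[2])
    expect_equal(gaussian_kl(p1, p2),
                 quadrature_kl_1d(mu[1], lv[1], mu[2], lv[2]), tolerance = 1e-6)
  }
})

test_that("prior KL is the closed-form divergence to the standard normal", {
  expect_equal(kl_to_prior(gaussian_posterior(rep(0, 4), rep(0, 4))), 0)
  expect_equal(kl_to_prior(gaussian_posterior(c(1, 0, 0), c(0, 0, 0))), 0.5)
  set.seed(13)
  post <- gaussian_posterior(matrix(rnorm(12), 3), matrix(rnorm(12, 0, 0.5), 3))
  std <- gaussian_posterior(matrix(0, 3, 4), matrix(0, 3, 4))
  expect_equal(kl_to_prior(post), mean(gaussian_kl(post, std)))
})

test_that("pairwise KL penalty equals the double-loop oracle", {
  set.seed(14)
  mu <- matrix(rnorm(8 * 3), 8); lv <- matrix(rnorm(8 * 3, 0, 0.5), 8)
  post <- gaussian_posterior(mu, lv)
  oracle <- loop_pairwise_kl(mu, lv)
  expect_equal(pairwise_kl_penalty(post), oracle, tolerance = 1e-10)
  # permutation invariance
  perm <- sample(8)
  expect_equal(pairwise_kl_penalty(gaussian_posterior(mu[perm, ], lv[perm, ])),
               oracle, tolerance = 1e-10)
  # identical posteriors: zero
  same <- gaussian_posterior(mu[rep(1, 5), ], lv[rep(1, 5), ])
  expect_equal(pairwise_kl_penalty(same), 0, tolerance = 1e-12)
  # normalization variants are fixed rescalings
  expect_equal(pairwise_kl_penalty(post, "sum"), oracle * 8 * 7)
  expect_equal(pairwise_kl_penalty(post, "cells"), oracle * 7)
  expect_error(pairwise_kl_penalty(gaussian_posterior(mu[1, ], lv[1, ])),
               ">= 2")
})

test_that("latent sampling is reparameterized and seed-stable", {
  post <- gaussian_posterior(matrix(c(2, -1), 1), matrix(c(-30, -30), 1))
  expect_equal(as.numeric(sample_latent(post, 1)), c(2, -1), tolerance = 1e-6)
  p2 <- gaussian_posterior(matrix(1.5, 1e5, 1), matrix(log(0.25), 1e5, 1))
  z <- sample_latent(p2, seed = 4)
  se <- 0.5 / sqrt(1e5)
  expect_lt(abs(mean(z) - 1.5), 3 * se)
  expect_identical(sample_latent(p2, seed = 4), z)
})

test_that("annealing schedule ramps and holds as specified", {
  expect_equal(kl_weight(0, 10, 4, 100), 0)
  expect_equal(kl_weight(9, 10, 4, 100), 0)
  # cycles of length (100-10)/4 = 22.5: quarter-point 0.5, midpoint 1, end 1
  expect_equal(kl_weight(10, 10, 4, 100), 0)
  expect_equal(kl_weight(10 + 22.5 / 4, 10, 4, 100), 0.5)
  expect_equal(kl_weight(10 + 22.5 / 2, 10, 4, 100), 1)
  expect_equal(kl_weight(32, 10, 4, 100), 1) # last epoch of cycle 1
  expect_equal(kl_weight(99, 10, 4, 100), 1) # last epoch overall
  expect_error(kl_weight(100, 10, 4, 100), "epoch")
  expect_error(kl_weight(5, 100, 4, 100), "warmup")
  expect_error(kl_weight(5, 2, 0, 100), "n_cycles")
})

test_that("total loss reduces correctly at the lambda/beta corners", {
  tt <- tiny_trained()
  X <- as.matrix(tt$fb$matrix$counts[1:16, ])
  C <- tt$conf$combined[1:16, ]
  om <- tt$model$omega
  l0 <- total_loss(X, C, tt$model, om, lambda = 0, beta = 1, seed = 3)
  # conditional-VAE objective: KL-to-prior + reconstruction, term by term
  expect_equal(l0$total, l0$kl_prior + l0$recon, tolerance = 1e-10)
  lb0 <- total_loss(X, C, tt$model, om, lambda = 1, beta = 0, seed = 3)
  expect_equal(lb0$total, 2 * lb0$recon, tolerance = 1e-10)
  lf <- total_loss(X, C, tt$model, om, lambda = 1, beta = 0.7, seed = 3,
                   pairwise_normalize = "cells")
  expect_equal(lf$total,
               0.7 * (lf$kl_prior + lf$kl_pairwise) + 2 * lf$recon,
               tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  set.seed(15)
  B <- 5L; n <- 7L; d <- 3L; nc <- 2L
  cfgs <- train_config(d = d, hidden_sizes = c(6L, 5L), epochs = 2, seed = 7)
  params <- invatac:::init_params(n, nc, cfgs)
  X <- matrix(rbinom(B * n, 1, 0.4), B, n)
  C <- cbind(1, rnorm(B))
  eps <- matrix(rnorm(B * d), B, d)
  omega <- 2.3; lambda <- 0.8; beta <- 0.9
  loss_fn <- function(p) {
    fe <- invatac:::forward_encoder(p, X)
    z <- fe$mu + exp(fe$lv / 2) * eps
    A <- invatac:::forward_decoder(p, z, C)$logits
    recon <- sum(omega * X * invatac:::softplus(-A) +
                   (1 - X) * invatac:::softplus(A)) / B
    klp <- mean(0.5 * rowSums(fe$mu^2 + exp(fe$lv) - 1 - fe$lv))
    klpair <- pairwise_kl_penalty(gaussian_posterior(fe$mu, fe$lv), "cells")
    beta * (klp + lambda * klpair) + (1 + lambda) * recon
  }
  st <- invatac:::invae_step(params, X, C, omega, lambda, beta, eps, "cells")
  h <- 1e-5
  check_tensor <- function(path_get, path_set, g) {
    w <- path_get(params)
    idx <- sample(length(w), min(6, length(w)))
    for (ii in idx) {
      pp <- params; wp <- w; wp[ii] <- w[ii] + h
      pp <- path_set(pp, wp); up <- loss_fn(pp)
      pm <- params; wm <- w; wm[ii] <- w[ii] - h
      pm <- path_set(pm, wm); dn <- loss_fn(pm)
      num <- (up - dn) / (2 * h)
      expect_equal(g[ii], num, tolerance = 1e-4)
    }
  }
  check_tensor(function(p) p$enc[[1]]$W,
               function(p, w) { p$enc[[1]]$W <- matrix(w, n); p },
               st$grads$enc[[1]]$W)
  check_tensor(function(p) p$mu_head$W,
               function(p, w) { p$mu_head$W <- matrix(w, 5); p },
               st$grads$mu_head$W)
  check_tensor(function(p) p$lv_head$W,
               function(p, w) { p$lv_head$W <- matrix(w, 5); p },
               st$grads$lv_head$W)
  check_tensor(function(p) p$dec[[1]]$W,
               function(p, w) { p$dec[[1]]$W <- matrix(w, d + nc); p },
               st$grads$dec[[1]]$W)
  check_tensor(function(p) p$dec[[3]]$W,
               function(p, w) { p$dec[[3]]$W <- matrix(w, 6); p },
               st$grads$dec[[3]]$W)
  check_tensor(function(p) p$enc[[2]]$b,
               function(p, w) { p$enc[[2]]$b <- w; p },
               st$grads$enc[[2]]$b)
})

test_that("encoding and decoding are deterministic with correct shapes", {
  tt <- tiny_trained()
  post <- encode(tt$model, tt$fb$matrix)
  expect_equal(ncol(post$mean), 4)
  expect_equal(nrow(post$mean), nrow(tt$fb$matrix$counts))
  post2 <- encode(tt$model, tt$fb$matrix)
  expect_identical(post$mean, post2$mean)
  # order preserved, duplicated input -> identical posterior rows
  X2 <- tt$fb$matrix$counts[c(1, 1, 2), ]
  p3 <- encode(tt$model, as.matrix(X2))
  expect_equal(p3$mean[1, ], p3$mean[2, ])
  expect_equal(p3$mean[3, ], post$mean[2, ])
  expect_error(encode(tt$model, matrix(0, 2, 5)), "dimension mismatch")
  z <- post$mean[1:3, ]
  cvec <- tt$conf$combined[1:3, ]
  xh <- decode(tt$model, z, cvec)
  expect_true(all(xh > 0 & xh < 1))
  expect_identical(decode(tt$model, z, cvec), xh)
  expect_error(decode(tt$model, z[, 1:2], cvec), "latent dimension")
})

test_that("training reduces the loss and is seed-reproducible", {
  tt <- tiny_trained()
  log <- tt$model$log
  expect_lt(log$total[nrow(log)], log$total[1])
  expect_true(all(is.finite(log$val_ll)))
  expect_true(all(log$kl_prior >= 0) && all(log$kl_pairwise >= -1e-9) &&
                all(log$recon >= 0))
  cfg <- train_config(d = 3, hidden_sizes = c(24L, 12L), epochs = 4,
                      minibatch_size = 32, seed = 42)
  m1 <- train_model(tt$fb$matrix, tt$conf, cfg)
  m2 <- train_model(tt$fb$matrix, tt$conf, cfg)
  expect_identical(m1$params$enc[[1]]$W, m2$params$enc[[1]]$W)
  expect_identical(m1$log$total, m2$log$total)
})

test_that("training config validates its invariants", {
  expect_error(train_config(d = 0), "d")
  expect_error(train_config(lambda_mi = -1), "lambda")
  expect_error(train_config(minibatch_size = 1), "minibatch")
  expect_error(train_config(omega = 0.5), "omega")
  expect_error(train_config(epochs = 10, warmup_epochs = 10), "warmup")
})
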