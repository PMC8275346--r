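test_that("dice coefficient follows its closed form", {
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(dice_coefficient(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  # symmetric for binary inputs, bounded for probabilistic ones
  set.seed(19)
  a <- rbinom(30, 1, 0.5); b <- rbinom(30, 1, 0.5)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  p <- runif(30)
  d <- dice_coefficient(a, p)
  expect_gte(d, 0); expect_lte(d, 1)
  expect_warning(z <- dice_coefficient(numeric(3), numeric(3)), "all-zero")
  expect_equal(z, 1)
  expect_error(dice_coefficient(c(1, 0), c(1, 0, 0)), "equal lengths")
  expect_error(dice_coefficient(c(2, 0), c(1, 0)), "binary")
})

test_that("MI estimator is calibrated on the Gaussian family", {
  set.seed(20)
  n <- 5000
  x <- rnorm(n)
  for (r in c(0, 0.3, 0.6, 0.9)) {
    y <- r * x + sqrt(1 - r^2) * rnorm(n)
    expect_lt(abs(estimate_mi(x, y) - (-0.5 * log(1 - r^2))), 0.05)
  }
})

test_that("MI estimator handles independence, determinism and degeneracy", {
  set.seed(21)
  z <- rnorm(2000); cc <- rnorm(2000)
  expect_lt(abs(estimate_mi(z, cc)), 0.02)
  # perfectly informative binary confounder: MI = H(c) = ln 2
  g <- factor(rep(c("a", "b"), 1000))
  expect_lt(abs(estimate_mi(as.numeric(g == "a"), g) - log(2)), 0.02)
  # independent discrete confounder
  expect_lt(abs(estimate_mi(z, g)), 0.02)
  # constant inputs
  expect_equal(estimate_mi(rep(1, 100), rnorm(100)), 0)
  expect_equal(estimate_mi(rnorm(100), rep(1, 100)), 0)
  expect_equal(estimate_mi(rnorm(100), factor(rep("a", 100))), 0)
  # deterministic given inputs
  expect_identical(estimate_mi(z, cc), estimate_mi(z, cc))
})

test_that("MI profile averages per-dimension estimates with clamping", {
  set.seed(22)
  emb <- matrix(rnorm(800 * 4), 800)
  conf <- rnorm(800)
  prof <- mi_profile(emb, conf)
  expect_length(prof$per_dim, 4)
  expect_equal(prof$mean, mean(prof$per_dim))
  expect_true(all(prof$per_dim >= 0))
  # joint shuffling of the cells leaves the estimate unchanged
  perm <- sample(800)
  prof2 <- mi_profile(emb[perm, ], conf[perm])
  expect_equal(prof2$mean, prof$mean, tolerance = 1e-9)
  # an informative dimension raises the profile; shuffling c kills it
  emb2 <- cbind(conf + 0.3 * rnorm(800), emb[, 2:4])
  expect_gt(mi_profile(emb2, conf)$mean, 0.2)
  expect_lt(mi_profile(emb2, sample(conf))$mean, 0.03)
})

test_that("clustering agreement matches independent references", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(unname(cluster_agreement(a, a)), c(1, 1))
  # all singletons vs all-in-one: chance-corrected zero
  expect_equal(unname(cluster_agreement(1:4, rep(1, 4))["ari"]), 0)
  set.seed(23)
  pr <- sample(1:5, 1000, replace = TRUE)
  tr <- sample(1:5, 1000, replace = TRUE)
  expect_lt(abs(cluster_agreement(pr, tr)["ari"]), 0.02)
  # invariant to relabeling either partition
  relab <- c(3, 1, 2)[a]
  expect_equal(cluster_agreement(relab, a), cluster_agreement(a, a))
  # independent oracle for the adjusted Rand index
  skip_if_not_installed("mclust")
  pr2 <- sample(1:4, 300, replace = TRUE)
  tr2 <- c(pr2[1:200], sample(1:4, 100, replace = TRUE))
  expect_equal(unname(cluster_agreement(pr2, tr2)["ari"]),
               mclust::adjustedRandIndex(pr2, tr2), tolerance = 1e-12)
  expect_error(cluster_agreement(1:3, 1:4), "equal lengths")
})
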