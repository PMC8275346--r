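test_that("archetype placement respects overlap geometry", {
  cfg0 <- sim_config(n_cells_per_type = c(5, 5), n_bins = 10, peaks_per_type = 3,
                     peak_overlap_fraction = 0, mu = 10, sigma = 1.5, rho = 0.5,
                     seed = 1)
  sets <- make_archetypes(cfg0)
  expect_length(sets, 2)
  expect_length(intersect(sets[[1]], sets[[2]]), 0)
  expect_length(sets[[1]], 3)

  cfg1 <- sim_config(n_cells_per_type = c(5, 5, 5), n_bins = 10, peaks_per_type = 3,
                     peak_overlap_fraction = 1, mu = 10, sigma = 1.5, rho = 0.5,
                     seed = 1)
  sets1 <- make_archetypes(cfg1)
  expect_identical(sets1[[1]], sets1[[2]])
  expect_identical(sets1[[2]], sets1[[3]])

  cfg13 <- sim_config(n_cells_per_type = c(5, 5, 5), n_bins = 30, peaks_per_type = 3,
                      peak_overlap_fraction = 1 / 3, mu = 10, sigma = 1.5,
                      rho = 0.5, seed = 2)
  sets13 <- make_archetypes(cfg13)
  shared <- Reduce(intersect, sets13)
  expect_length(shared, 1)
  expect_true(all(lengths(sets13) == 3))
})

test_that("archetype placement is deterministic and checks feasibility", {
  cfg <- sim_config(n_cells_per_type = c(4, 4), n_bins = 50, peaks_per_type = 10,
                    peak_overlap_fraction = 0.2, mu = 10, sigma = 1.5, rho = 0.5,
                    seed = 9)
  expect_identical(make_archetypes(cfg), make_archetypes(cfg))
  bad <- sim_config(n_cells_per_type = rep(4, 5), n_bins = 12, peaks_per_type = 3,
                    peak_overlap_fraction = 0, mu = 10, sigma = 1.5, rho = 0.5)
  expect_error(make_archetypes(bad), "infeasible")
})

test_that("depth sampling follows the log-normal law", {
  # zero-spread limit: every count collapses to the median
  expect_true(all(sample_cell_depths(500, 1 + 1e-9, 50, seed = 1) == 500))
  # mu is the median of the law
  d <- sample_cell_depths(5000, 1.5, 10000, seed = 3)
  expect_lt(abs(median(d) / 5000 - 1), 0.02)
  expect_true(all(d >= 1))
  # Kolmogorov-Smirnov against the stated law (alpha = 0.01)
  ks <- suppressWarnings(ks.test(log(d), "pnorm", log(5000), log(1.5)))
  expect_gt(ks$p.value, 0.01)
  expect_identical(d, sample_cell_depths(5000, 1.5, 10000, seed = 3))
  expect_error(sample_cell_depths(5000, 1, 10), "sigma")
  expect_error(sample_cell_depths(-1, 1.5, 10), "mu")
})

test_that("read placement respects the signal-to-noise ratio", {
  peaks <- list(a = c(2L, 5L, 9L), b = c(11L, 14L, 17L))
  labs <- c("a", "a", "b")
  depths <- c(200, 150, 180)
  m1 <- simulate_cells(peaks, depths, rho = 1, n_bins = 20, labs, seed = 1)
  expect_equal(unname(Matrix::rowSums(m1)), depths) # row sums = depths exactly
  expect_true(all(which(m1[1, ] > 0) %in% peaks$a))
  expect_true(all(which(m1[3, ] > 0) %in% peaks$b))
  m0 <- simulate_cells(peaks, depths, rho = 0, n_bins = 20, labs, seed = 1)
  expect_equal(sum(m0[1, peaks$a]), 0)
  expect_equal(sum(m0[3, peaks$b]), 0)
  # rho = 0.4 at depth 5000: realized in-peak fraction inside a 99% binomial CI
  big <- simulate_cells(list(a = 1:50), 5000, rho = 0.4, n_bins = 5000, "a",
                        seed = 7)
  frac <- sum(big[1, 1:50]) / 5000
  ci <- qbinom(c(0.005, 0.995), 5000, 0.4) / 5000
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  expect_error(simulate_cells(peaks, 100, 0.5, 20, "zz", 1), "peak set")
  expect_identical(m1, simulate_cells(peaks, depths, 1, 20, labs, seed = 1))
})

test_that("experiment presets reproduce the study designs", {
  p1 <- sim_preset("sim1", seed = 1)
  expect_equal(sum(p1$batches[[1]]$n_cells_per_type), 10000)
  expect_equal(p1$batches[[1]]$n_cells_per_type[5], 100) # 1% rare type
  expect_equal(p1$batches[[1]]$mu, 5000)
  expect_equal(p1$batches[[1]]$rho, 0.4)
  p2 <- sim_preset("sim2", seed = 1)
  expect_equal(p2$n_types, 9)
  expect_equal(p2$batches[[1]]$mu, 3000)
  p3 <- sim_preset("sim3", seed = 1)
  expect_equal(vapply(p3$batches, `[[`, numeric(1), "mu"), c(2500, 5000))
  expect_equal(vapply(p3$batches, `[[`, numeric(1), "rho"), c(0.4, 0.5))
  # batch-exclusive rare types
  expect_equal(p3$batches[[1]]$n_cells_per_type[6], 0)
  expect_equal(p3$batches[[2]]$n_cells_per_type[5], 0)
})

test_that("simulated datasets carry consistent ground truth", {
  cfg <- sim_preset("sim3", cells = 240, genome_scale = 0.03, seed = 4)
  ds <- simulate_experiment(cfg)
  expect_equal(unname(Matrix::rowSums(ds$matrix$counts)), ds$depths)
  expect_equal(ds$matrix$depths, ds$depths)
  # bulk_profiles[t, j] = 1 iff bin j in peak set of type t
  for (t in seq_along(ds$peak_sets)) {
    expect_equal(which(ds$bulk_profiles[t, ] == 1),
                 sort(ds$peak_sets[[t]]))
  }
  expect_equal(length(unique(ds$batch_ids)), 2)
  # same seed, bit-identical output
  ds2 <- simulate_experiment(cfg)
  expect_identical(ds$matrix$counts, ds2$matrix$counts)
  expect_identical(ds$depths, ds2$depths)
})

test_that("pure-signal single-type cells stay inside the bulk profile", {
  cfg <- sim_config(n_cells_per_type = 30, n_bins = 400, peaks_per_type = 40,
                    peak_overlap_fraction = 0, mu = 80, sigma = 1.3, rho = 1,
                    seed = 8)
  ds <- simulate_experiment(cfg)
  bin <- binarize(ds$matrix)
  bulk <- as.numeric(ds$bulk_profiles[1, ])
  for (i in seq_len(nrow(bin$counts)))
    expect_true(all(bulk[which(bin$counts[i, ] > 0)] == 1))
})
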