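test_that("simulation is reproducible and validates its config", {
  a <- small_sim(seed = 9)
  b <- small_sim(seed = 9)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 10)
  expect_false(identical(a$counts$values, c$counts$values))

  expect_error(sim_config(frac_perturbed = 0), "frac_perturbed")
  expect_error(sim_config(knockdown_factor = 1), "knockdown_factor")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_genes = 5, n_signature = 5), "n_signature")
})

test_that("perturbed mask follows the requested penetrance", {
  sim <- simulate_cropseq(sim_config(n_control = 2L, n_targeted = 10000L,
                                     n_genes = 25L, n_signature = 3L,
                                     frac_perturbed = 0.5, seed = 21))
  expect_equal(mean(sim$truth$perturbed_mask), 0.5, tolerance = 0.02 / 0.5)
  # degenerate fraction: every targeted cell perturbed
  sim1 <- small_sim(seed = 3, frac_perturbed = 1.0)
  expect_true(all(sim1$truth$perturbed_mask))
})

test_that("counts follow the negative-binomial mean-dispersion law", {
  # the target gene's mean is pinned, so its control-cell counts give a
  # large sample at known mu and theta
  mu <- 10; theta <- 2
  sim <- simulate_cropseq(sim_config(
    n_control = 100000L, n_targeted = 1L, n_genes = 5L, n_signature = 1L,
    target_log_mean = log(mu), dispersion = theta, seed = 22))
  x <- sim$counts$values[seq_len(100000), sim$truth$target_gene_index]
  expect_equal(mean(x), mu, tolerance = 0.05)
  expect_equal(var(x), mu + mu^2 / theta, tolerance = 0.1)
})

test_that("knock-down hits every targeted cell, signature only perturbed ones", {
  cfg <- sim_config(n_control = 400L, n_targeted = 400L, n_genes = 30L,
                    n_signature = 3L, frac_perturbed = 0.5,
                    knockdown_factor = 0.1, knockdown_sd = 0, seed = 23)
  sim <- simulate_cropseq(cfg)
  tr <- sim$truth
  ctrl <- sim$counts$values[1:400, ]
  targ <- sim$counts$values[401:800, ]
  # target gene knocked down ~10x in targeted cells, perturbed or not
  expect_lt(mean(targ[, tr$target_gene_index]),
            0.3 * mean(ctrl[, tr$target_gene_index]))
  expect_lt(mean(targ[!tr$perturbed_mask, tr$target_gene_index]),
            0.3 * mean(ctrl[, tr$target_gene_index]))
  # signature genes shifted only in the perturbed subset, in direction
  for (k in seq_along(tr$signature_gene_indices)) {
    g <- tr$signature_gene_indices[k]
    gap_pert <- mean(targ[tr$perturbed_mask, g]) - mean(ctrl[, g])
    expect_equal(sign(gap_pert), tr$signature_directions[k])
    gap_non <- abs(mean(targ[!tr$perturbed_mask, g]) - mean(ctrl[, g]))
    expect_lt(gap_non, abs(gap_pert))
  }
})

test_that("expected signature gap grows with the planted fold change", {
  cfg1 <- sim_config(signature_lfc = 1, seed = 31, n_genes = 50L,
                     n_signature = 4L, n_control = 5L, n_targeted = 5L)
  cfg2 <- sim_config(signature_lfc = 2, seed = 31, n_genes = 50L,
                     n_signature = 4L, n_control = 5L, n_targeted = 5L)
  t1 <- simulate_cropseq(cfg1)$truth
  t2 <- simulate_cropseq(cfg2)$truth
  # same seed -> same baseline means and gene choices; only lfc differs
  expect_identical(t1$signature_gene_indices, t2$signature_gene_indices)
  expect_true(all(abs(expected_signature_gap(cfg2, t2)) >
                  abs(expected_signature_gap(cfg1, t1))))
})

test_that("null simulation carries no perturbation at all", {
  sim <- simulate_null(sim_config(n_control = 50L, n_targeted = 50L,
                                  n_genes = 20L, n_signature = 2L, seed = 41))
  expect_true(all(!sim$truth$perturbed_mask))
  expect_length(sim$truth$signature_gene_indices, 0)
  expect_identical(sim$truth$knockdown_efficiency, rep(1, 50))
  # same seed: the targeted block of the null equals the cropseq baseline
  # for all non-target, non-signature genes (identical generative stream)
  expect_equal(dim(sim$counts$values), c(100L, 20L))
})
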