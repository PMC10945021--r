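test_that("attribution is exact for a fixed-ReLU-region (linear) network", {
  # positive weights and large positive biases keep every ReLU active on
  # nonnegative inputs, so the class-1 logit is linear: f(x) = x %*% coef + c
  d <- 6; h <- 4
  set.seed(50)
  w <- ssae_init(d, h, seed = 50)
  w$W1 <- matrix(runif(d * h, 0.1, 0.5), d, h)
  w$b1 <- rep(5, h)
  coef <- as.vector(w$W1 %*% w$W2[, 2])

  X_eval <- matrix(rpois(5 * d, 4), 5, d)
  baseline <- rpois(d, 2)
  res <- ssaescreen:::attribute_cells_signed(w, X_eval, baseline, n_steps = 4)
  # per-gene closed form: (x - b) * coef
  expect_equal(res$attributions,
               sweep(X_eval - matrix(baseline, 5, d, byrow = TRUE), 2, coef, "*"),
               tolerance = 1e-10)
  # completeness: attributions sum to the logit difference
  expect_equal(rowSums(res$attributions),
               res$logit_eval - rep(res$logit_baseline, 5),
               tolerance = 1e-8)
})

test_that("attribution completeness holds within 5% on a trained network", {
  ds <- small_dataset(seed = 16)
  fit <- train_double_descent(ds, tiny_train_config(seed = 16, eta = 8))
  X_eval <- ds$X[ds$Y == 1L, , drop = FALSE][1:10, ]
  baseline <- colMeans(ds$X[ds$Y == 0L, , drop = FALSE])
  res <- ssaescreen:::attribute_cells_signed(fit$weights, X_eval, baseline,
                                             n_steps = 50)
  total <- rowSums(res$attributions)
  diff <- res$logit_eval - rep(res$logit_baseline, nrow(X_eval))
  expect_lt(max(abs(total - diff) / pmax(abs(diff), 0.1)), 0.05)
})

test_that("genes with zeroed first-layer rows get exactly zero attribution", {
  ds <- small_dataset(seed = 17)
  fit <- train_double_descent(ds, tiny_train_config(seed = 17, eta = 4))
  attr <- attribute_features(fit$weights, ds$X[ds$Y == 1L, ],
                             ds$X[ds$Y == 0L, ], n_baseline_samples = 3,
                             seed = 1)
  expect_true(any(!fit$support))
  expect_true(all(attr[!fit$support] == 0))
  expect_error(attribute_features(fit$weights, ds$X, ds$X[0, , drop = FALSE],
                                  3, 1), "empty baseline")
})

test_that("rank aggregation computes means and sds over runs", {
  r1 <- c(a = 1, b = 2, c = 3)
  expect_equal(aggregate_ranks(list(r1, r1, r1))$mean_rank, c(1, 2, 3))
  expect_equal(aggregate_ranks(list(r1, r1, r1))$sd_rank, c(0, 0, 0))

  r <- list(c(a = 1, b = 2), c(a = 500, b = 2), c(a = 1000, b = 2))
  agg <- aggregate_ranks(r)
  # frozen from the direct formula: mean (1+500+1000)/3, sd
  # sqrt(((1-m)^2+(500-m)^2+(1000-m)^2)/2) with m = 500.3333
  expect_equal(agg$mean_rank[1], 500.3333, tolerance = 1e-4)
  expect_equal(agg$sd_rank[1], 499.5004, tolerance = 1e-4)

  expect_error(aggregate_ranks(list(r1)), "at least two")
  expect_error(aggregate_ranks(list(r1, c(a = 1, b = 2))), "gene universes")
})

test_that("rank aggregation is permutation-equivariant in gene order", {
  set.seed(51)
  r1 <- sample(10); r2 <- sample(10)
  names(r1) <- names(r2) <- letters[1:10]
  agg <- aggregate_ranks(list(r1, r2))
  perm <- sample(10)
  agg_p <- aggregate_ranks(list(r1[perm], r2[perm]))
  expect_equal(agg_p$mean_rank, agg$mean_rank[perm])
  expect_equal(agg_p$sd_rank, agg$sd_rank[perm])
})

test_that("attribution ranks give selected genes 1..s and others the worst rank", {
  attr <- c(g1 = 0.5, g2 = 0.9, g3 = 0, g4 = 0.1)
  support <- c(TRUE, TRUE, FALSE, TRUE)
  r <- ssaescreen:::attribution_ranks(attr, support)
  expect_equal(unname(r), c(2, 1, 4, 3))
})

test_that("log2 fold changes follow the closed form on controlled data", {
  # equal library sizes make the normalization a no-op
  X <- rbind(matrix(c(2, 8), 10, 2, byrow = TRUE),
             matrix(c(8, 2), 10, 2, byrow = TRUE))
  ds <- manual_dataset(X, c(rep(0L, 10), rep(1L, 10)))
  lfc <- compute_log2fc(ds, perturbed_indices = 11:20, pseudocount = 0)
  expect_equal(unname(lfc), c(2, -2))  # log2(8/2), log2(2/8)

  # identical groups: all zero
  ds_same <- manual_dataset(rbind(X[1:10, ], X[1:10, ]),
                            c(rep(0L, 10), rep(1L, 10)))
  expect_equal(unname(compute_log2fc(ds_same, 11:20)), c(0, 0))

  # zero mean in the perturbed group with pseudocount 1
  X2 <- rbind(matrix(c(4, 4), 10, 2, byrow = TRUE),
              matrix(c(0, 8), 10, 2, byrow = TRUE))
  ds2 <- manual_dataset(X2, c(rep(0L, 10), rep(1L, 10)))
  expect_equal(unname(compute_log2fc(ds2, 11:20, pseudocount = 1))[1],
               log2(1 / 5))
})

test_that("signature assembly ranks, annotates and flags stability", {
  log2fc <- c(g1 = 1.5, g2 = -0.8, g3 = 0.2, g4 = -2)
  rank1 <- c(g1 = 1, g2 = 2, g3 = 4, g4 = 3)
  rank2 <- c(g1 = 1, g2 = 3, g3 = 4, g4 = 2)
  attr <- c(g1 = 1, g2 = 0.4, g3 = 0, g4 = 0.5)
  sig <- build_signature(list(attr, attr), list(rank1, rank2), log2fc,
                         top_n = 3, sd_threshold = 0.5)
  expect_equal(sig$gene[1], "g1")
  expect_equal(sig$direction[1], "up")
  expect_true(sig$stable[1])       # sd 0
  expect_false(sig$stable[sig$gene == "g2"])  # sd ~0.7 > 0.5
  expect_equal(nrow(sig), 3)

  # top_n larger than the ever-selected pool: truncated with a warning
  rank_d <- c(g1 = 1, g2 = 2, g3 = 4, g4 = 4)  # g3, g4 never selected (d=4)
  expect_warning(
    sig2 <- build_signature(list(attr, attr), list(rank_d, rank_d), log2fc,
                            top_n = 3, sd_threshold = 1),
    "ever selected")
  expect_equal(nrow(sig2), 2)
})
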