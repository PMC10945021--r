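test_that("train_config validates fields", {
  expect_error(train_config(eta = 0), "eta")
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(n_folds = 1), "folds")
  expect_error(train_config(lambda = -0.1), "lambda")
})

test_that("compiled and reference descent engines agree", {
  ds <- small_dataset(seed = 5)
  cfg <- tiny_train_config(seed = 5, eta = 6)
  fr <- train_double_descent(ds, cfg, seed = 2, engine = "r")
  fc <- train_double_descent(ds, cfg, seed = 2, engine = "cpp")
  expect_identical(fr$support, fc$support)
  for (nm in names(fr$weights)) {
    expect_equal(fc$weights[[nm]], fr$weights[[nm]], tolerance = 1e-10)
  }
  expect_equal(fc$trace$total, fr$trace$total, tolerance = 1e-10)
})

test_that("double descent freezes deselected genes and obeys the constraint", {
  ds <- small_dataset(seed = 6)
  cfg <- tiny_train_config(seed = 6, eta = 3)
  fit <- train_double_descent(ds, cfg)
  # the constraint holds on the returned first layer
  expect_lte(sum(abs(fit$weights$W1)), cfg$eta * (1 + 1e-6))
  # frozen rows are exactly zero after phase 2
  expect_true(any(!fit$support))
  expect_true(all(fit$weights$W1[!fit$support, ] == 0))

  # eta larger than the initial norm: projection never binds, support full
  init_norm <- sum(abs(ssae_init(ncol(ds$X), cfg$hidden_dim, seed = cfg$seed)$W1))
  cfg_wide <- tiny_train_config(seed = 6, eta = 100 * init_norm)
  fit_wide <- train_double_descent(ds, cfg_wide)
  expect_true(all(fit_wide$support))

  # single-class data is rejected
  ds1 <- ds
  ds1$Y <- rep(1L, length(ds$Y))
  expect_error(train_double_descent(ds1, cfg), "single class")
})

test_that("selected-feature count grows with eta after training", {
  ds <- small_dataset(seed = 12)
  n_sel <- vapply(c(1, 5, 20, 80), function(eta) {
    sum(train_double_descent(ds, tiny_train_config(seed = 12, eta = eta))$support)
  }, 1)
  expect_true(all(diff(n_sel) >= 0))
})

test_that("cross-validation reports the full fold-by-seed grid", {
  ds <- small_dataset(seed = 7)
  cfg <- tiny_train_config(seed = 7, n_folds = 3L, n_seeds = 2L)
  rep <- crossvalidate(ds, cfg)
  expect_equal(nrow(rep$records), 6)
  expect_equal(rep$accuracy_mean, mean(rep$records$accuracy))
  expect_equal(rep$f1_mean, mean(rep$records$f1))
  # out-of-fold scores cover every cell for every seed
  expect_false(anyNA(rep$oof_scores))
  expect_true(all(rep$oof_scores >= 0 & rep$oof_scores <= 1))
  expect_equal(dim(rep$oof_scores), c(length(ds$Y), 2L))

  # reproducibility: identical config reproduces the report exactly
  rep2 <- crossvalidate(ds, cfg)
  expect_equal(rep$records, rep2$records, tolerance = 1e-12)
  expect_equal(rep$oof_scores, rep2$oof_scores, tolerance = 1e-12)
})

test_that("classes too small for stratified folds are rejected", {
  X <- matrix(rpois(13 * 6, 4), 13, 6)
  ds <- manual_dataset(X, c(rep(0L, 10), rep(1L, 3)))
  expect_error(crossvalidate(ds, tiny_train_config(n_folds = 4L)),
               "insufficient cells")
})

test_that("strongly separated classes are classified near-perfectly", {
  # controls ~ Pois(1), targeted cells with 5 genes at huge counts
  set.seed(88)
  X <- matrix(rpois(120 * 30, 1), 120, 30)
  X[61:120, 1:5] <- X[61:120, 1:5] + matrix(rpois(60 * 5, 60), 60, 5)
  ds <- manual_dataset(X, c(rep(0L, 60), rep(1L, 60)))
  rep <- crossvalidate(ds, tiny_train_config(seed = 1, eta = 10,
                                             epochs_phase1 = 15L,
                                             epochs_phase2 = 15L))
  expect_gte(rep$accuracy_mean, 0.98)
})

test_that("golden-section search maximizes a concave objective", {
  res <- tune_eta(NULL, NULL, 0.01, 10, max_evals = 20,
                  objective = function(eta) -(eta - 5)^2)
  expect_equal(res$eta, 5, tolerance = 0.1)
  expect_lte(nrow(res$trace), 20)
  expect_error(tune_eta(NULL, NULL, 5, 5), "eta_low")

  # flat objective: evaluations stay in the bracket and the candidate
  # interval shrinks by the golden ratio each iteration
  flat <- tune_eta(NULL, NULL, 1, 2, max_evals = 12,
                   objective = function(eta) 1)
  expect_true(all(flat$trace$eta >= 1 & flat$trace$eta <= 2))
  gr <- (sqrt(5) - 1) / 2
  spread <- abs(diff(tail(flat$trace$eta, 2)))
  expect_lt(spread, (2 - 1) * gr^9)
})
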