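test_that("softmax matches closed forms and is overflow-safe", {
  expect_equal(softmax_scores(rbind(c(0, 0)))[1, ], c(0.5, 0.5))
  expect_equal(softmax_scores(rbind(c(log(3), 0)))[1, ], c(0.75, 0.25))
  big <- softmax_scores(rbind(c(1000, 0)))
  expect_true(all(is.finite(big)))
  expect_equal(big[1, 1], 1, tolerance = 1e-12)
  set.seed(1)
  S <- softmax_scores(matrix(rnorm(40, sd = 5), 10, 4))
  expect_equal(rowSums(S), rep(1, 10), tolerance = 1e-6)
})

test_that("Huber loss has the right branches and is continuous", {
  expect_equal(huber_loss(0.5, 1), 0.125)
  expect_equal(huber_loss(2, 1), 1.5)
  # the two branches agree at |r| = delta
  d <- 0.7
  expect_equal(0.5 * d^2 / d, d - 0.5 * d)
  expect_equal(huber_loss(d, d), 0.5 * d)
  # mean reduction over a matrix
  expect_equal(huber_loss(matrix(c(0.5, 2), 1), 1), (0.125 + 1.5) / 2)
})

test_that("forward pass computes the documented architecture", {
  w <- ssae_init(3, hidden_dim = 2, seed = 1)
  X <- matrix(c(1, 2, 3), 1, 3)

  # all-zero weights: zero latent, maximally uncertain scores
  w0 <- lapply(w, function(p) p * 0)
  class(w0) <- "ssae_weights"
  out0 <- ssae_forward(w0, X)
  expect_equal(out0$Z, matrix(0, 1, 2))
  expect_equal(out0$scores[1, ], c(0.5, 0.5))

  # hand-computed forward on toy weights
  wt <- w0
  wt$W1 <- matrix(1, 3, 2); wt$b1 <- c(0.5, -10)
  wt$W2 <- rbind(c(1, -1), c(0, 0)); wt$b2 <- c(0, 0.25)
  wt$W3 <- matrix(1, 2, 2); wt$b3 <- c(0, -100)
  wt$W4 <- rbind(c(1, 0, 0), c(0, 1, 0)); wt$b4 <- c(0, 0, 1)
  h1 <- c(max(6 + 0.5, 0), max(6 - 10, 0))          # (6.5, 0)
  z <- c(h1 %*% rbind(c(1, -1), c(0, 0))) + c(0, 0.25)  # (6.5, -6.25)
  h2 <- pmax(c(sum(z), sum(z) - 100), 0)            # (0.25, 0)
  xhat <- c(h2[1], h2[2], 0) + c(0, 0, 1)
  out <- ssae_forward(wt, X)
  expect_equal(out$Z[1, ], z)
  expect_equal(out$X_hat[1, ], xhat)
  expect_equal(out$scores[1, ], exp(z) / sum(exp(z)), tolerance = 1e-12)

  expect_error(ssae_forward(w, matrix(1, 1, 5)), "expects")
})

test_that("joint loss decomposes into CE and reconstruction", {
  set.seed(2)
  X <- matrix(rpois(40, 3), 5, 8)
  Y <- c(0L, 1L, 0L, 1L, 1L)
  w <- ssae_init(8, 4, seed = 2)
  out <- ssae_forward(w, X)
  ls <- ssae_loss(out, X, Y, lambda = 0)
  expect_equal(ls$total, ls$ce)  # lambda = 0: pure cross-entropy
  ls1 <- ssae_loss(out, X, Y, lambda = 1)
  expect_equal(ls1$total, ls1$ce + ls1$reconstruction)
  expect_gte(ls1$reconstruction, 0)

  # perfect reconstruction zeroes the Huber term
  out_perfect <- out
  out_perfect$X_hat <- X
  expect_equal(ssae_loss(out_perfect, X, Y)$reconstruction, 0)

  # near-one-hot correct scores: CE ~ 0
  out_hot <- out
  out_hot$scores <- cbind(1 - Y, Y) * (1 - 1e-9) + 1e-9 / 2
  expect_lt(ssae_loss(out_hot, X, Y)$ce, 1e-6)

  expect_error(ssae_loss(out, X, Y, lambda = -1), "nonnegative")
})

test_that("accuracy and F1 follow the contingency-table formulas", {
  Y <- c(rep(1L, 10), rep(0L, 10))
  perfect <- cbind(1 - Y, Y)
  expect_equal(accuracy_f1(perfect, Y), c(accuracy = 1, f1 = 1))
  # degenerate predictor: everything class 0
  all0 <- cbind(rep(1, 20), rep(0, 20))
  expect_equal(accuracy_f1(all0, Y), c(accuracy = 0.5, f1 = 0))
  # TP=9 FP=1 FN=1 TN=9 -> accuracy 0.9, F1 0.9
  pred <- c(rep(1L, 9), 0L, rep(0L, 9), 1L)
  scores <- cbind(1 - pred, pred)
  expect_equal(accuracy_f1(scores, Y), c(accuracy = 0.9, f1 = 0.9))
})

test_that("analytic gradients match central finite differences", {
  set.seed(3)
  X <- matrix(rpois(40, 4), 5, 8)
  Y <- c(0L, 1L, 0L, 1L, 1L)
  w <- ssae_init(8, 6, seed = 3)
  cw <- c(1.25, 0.85)
  g <- ssaescreen:::ssae_gradients(w, X, Y, lambda = 0.7, delta = 1.3,
                                   class_weights = cw)
  loss_at <- function(w) {
    ssae_loss(ssae_forward(w, X), X, Y, lambda = 0.7, delta = 1.3,
              class_weights = cw)$total
  }
  eps <- 1e-5
  for (nm in names(g)) {
    idx <- sample(length(g[[nm]]), min(4, length(g[[nm]])))
    for (i in idx) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
      denom <- max(abs(fd), abs(g[[nm]][i]), 1e-6)
      expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-4)
    }
  }
})
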