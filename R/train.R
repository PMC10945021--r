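## Projected double-descent training of the SSAE, stratified
## cross-validated evaluation, and golden-section tuning of the sparsity
## radius eta.

#' Training configuration
#'
#' @param lambda Reconstruction trade-off in the joint loss (default 1).
#' @param eta l1,1 constraint radius on the first encoder layer; smaller
#'   values select fewer genes. The default keeps roughly 10\% of a
#'   1000-gene panel; [tune_eta()] finds a dataset-specific optimum.
#' @param hidden_dim Hidden layer width h (default 100).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs_phase1,epochs_phase2 Epoch budgets of the two descents
#'   (default 15 each). Short budgets act as early stopping: longer
#'   training lets the network memorize noise genes to "explain" targeted
#'   cells that carry no detectable perturbation, which degrades control
#'   specificity and with it the selectivity of the perturbation score.
#' @param batch_size Minibatch size (default 128).
#' @param n_folds Cross-validation folds (default 4).
#' @param n_seeds Number of initialization seeds averaged over (default 3).
#' @param huber_delta Huber transition point (default 1).
#' @param class_weighting Weight the cross-entropy by inverse class
#'   frequency. Default `FALSE`: plain CE, matching a first round in which
#'   only the second round is explicitly balanced; with plain CE, targeted
#'   cells carrying no detectable perturbation score below 0.5 whenever
#'   controls are in the majority, which is what makes the perturbation
#'   score selective. Set `TRUE` to protect strongly imbalanced designs
#'   (many more targeted cells than controls) from majority-class collapse.
#' @param seed Run seed; fold assignment and every initialization derive
#'   their own sub-seed from it.
#' @return A validated `train_config` list.
#' @export
train_config <- function(lambda = 1, eta = 25, hidden_dim = 100L,
                         lr = 1e-3, epochs_phase1 = 15L, epochs_phase2 = 15L,
                         batch_size = 128L, n_folds = 4L, n_seeds = 3L,
                         huber_delta = 1, class_weighting = FALSE, seed = 1L) {
  cfg <- list(lambda = lambda, eta = eta, hidden_dim = as.integer(hidden_dim),
              lr = lr, epochs_phase1 = as.integer(epochs_phase1),
              epochs_phase2 = as.integer(epochs_phase2),
              batch_size = as.integer(batch_size),
              n_folds = as.integer(n_folds), n_seeds = as.integer(n_seeds),
              huber_delta = huber_delta,
              class_weighting = isTRUE(class_weighting),
              seed = as.integer(seed))
  if (cfg$lambda < 0) stopf("train_config: lambda must be nonnegative")
  if (cfg$eta <= 0) stopf("train_config: eta must be positive")
  if (cfg$lr <= 0) stopf("train_config: lr must be positive")
  if (cfg$n_folds < 2) stopf("train_config: need at least 2 folds")
  if (cfg$epochs_phase1 < 1 || cfg$epochs_phase2 < 1) {
    stopf("train_config: epoch counts must be >= 1")
  }
  if (cfg$n_seeds < 1) stopf("train_config: need at least 1 seed")
  structure(cfg, class = "train_config")
}

#' Read a training configuration from YAML
#'
#' @param path YAML file whose keys mirror [train_config()] arguments.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  if (!file.exists(path)) stopf("read_train_config: no file '%s'", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(train_config)))
  if (length(unknown)) {
    stopf("read_train_config: unknown field(s): %s",
          paste(unknown, collapse = ", "))
  }
  do.call(train_config, vals)
}

class_weights_for <- function(Y, enabled) {
  if (!enabled) return(c(1, 1))
  n <- length(Y)
  c(n / (2 * sum(Y == 0L)), n / (2 * sum(Y == 1L)))
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(p) p * 0),
       v = lapply(weights, function(p) p * 0),
       t = 0L)
}

## Adam with the usual bias correction; updates weights and moments in
## place through the C++ kernel (the caller owns deep copies).
adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    .adam_update_inplace(weights[[nm]], state$m[[nm]], state$v[[nm]],
                         grads[[nm]], lr, beta1, beta2, bc1, bc2, eps)
  }
  list(weights = weights, state = state)
}

## Per-epoch shuffled cell orders, drawn in R so that both descent engines
## see exactly the same minibatches for a given seed.
make_batch_order <- function(n, epochs, seed, phase_tag) {
  set.seed(derive_seed(seed, "batches", phase_tag))
  vapply(seq_len(epochs), function(e) sample.int(n), integer(n))
}

## One projected-Adam descent. support_mask (logical over genes) freezes
## deselected first-layer rows: their gradients are zeroed and the rows
## stay exactly zero. The l1,1 projection is applied to the first layer
## after every optimizer step so iterates remain feasible. The "cpp"
## engine is the production path; "r" is the plain-R reference the test
## suite checks it against.
run_descent <- function(weights, X, Y, config, epochs, phase_tag, seed,
                        support_mask = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- nrow(X)
  cw <- class_weights_for(Y, config$class_weighting)
  batch_order <- make_batch_order(n, epochs, seed, phase_tag)
  if (engine == "cpp") {
    res <- .run_descent_cpp(weights, X, as.integer(Y), config$lambda,
                            config$huber_delta, config$eta, config$lr,
                            config$batch_size, cw, batch_order,
                            support_mask)
    trace <- data.frame(phase = phase_tag, epoch = seq_len(epochs),
                        ce = res$ce, reconstruction = res$reconstruction,
                        total = res$ce + config$lambda * res$reconstruction,
                        selected_fraction = res$selected_fraction)
    res$weights$b1 <- as.numeric(res$weights$b1)
    res$weights$b2 <- as.numeric(res$weights$b2)
    res$weights$b3 <- as.numeric(res$weights$b3)
    res$weights$b4 <- as.numeric(res$weights$b4)
    return(list(weights = res$weights, trace = trace))
  }
  run_descent_r(weights, X, Y, config, epochs, phase_tag, batch_order,
                support_mask, cw)
}

run_descent_r <- function(weights, X, Y, config, epochs, phase_tag,
                          batch_order, support_mask, cw) {
  # deep-copy: the in-place Adam kernel must own this memory exclusively
  cls <- class(weights)
  weights <- lapply(weights, function(p) p + 0)
  class(weights) <- cls
  n <- nrow(X)
  state <- adam_init(weights)
  trace <- vector("list", epochs)
  for (epoch in seq_len(epochs)) {
    ord <- batch_order[, epoch]
    starts <- seq(1L, n, by = config$batch_size)
    ep_ce <- ep_rec <- ep_n <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx]
      out <- ssae_forward(weights, Xb)
      ls <- ssae_loss(out, Xb, Yb, config$lambda, config$huber_delta, cw)
      if (!is.finite(ls$total)) {
        stopf("training diverged (non-finite loss) at %s epoch %d",
              phase_tag, epoch)
      }
      ep_ce <- ep_ce + ls$ce * length(idx)
      ep_rec <- ep_rec + ls$reconstruction * length(idx)
      ep_n <- ep_n + length(idx)
      grads <- ssae_gradients(weights, Xb, Yb, config$lambda,
                              config$huber_delta, cw, out = out)
      if (!is.null(support_mask)) grads$W1[!support_mask, ] <- 0
      upd <- adam_step(weights, grads, state, config$lr)
      weights <- upd$weights
      state <- upd$state
      weights$W1 <- project_l11_bilevel(weights$W1, config$eta)
      if (!is.null(support_mask)) weights$W1[!support_mask, ] <- 0
    }
    ce <- ep_ce / ep_n
    rec <- ep_rec / ep_n
    trace[[epoch]] <- data.frame(
      phase = phase_tag, epoch = epoch, ce = ce, reconstruction = rec,
      total = ce + config$lambda * rec,
      selected_fraction = selected_feature_fraction(weights$W1))
  }
  list(weights = weights, trace = do.call(rbind, trace))
}

#' Double-descent projected training
#'
#' Lottery-ticket style two-phase optimization. Phase 1 trains the full
#' network with Adam, projecting the first encoder layer onto the l1,1
#' ball of radius `eta` after every step; the genes with nonzero rows at
#' the end form the support. The surviving first-layer rows are then
#' rewound to their initial values, deselected rows are frozen at exactly
#' zero, and phase 2 retrains the masked network under the same
#' projection.
#'
#' @param dataset A `labeled_dataset` with both classes present.
#' @param config A [train_config()].
#' @param seed Initialization/batching seed for this run (defaults to
#'   `config$seed`).
#' @param engine `"cpp"` (default) for the compiled training loop or
#'   `"r"` for the plain-R reference implementation; the two produce
#'   numerically identical results.
#' @return List with `weights` (`ssae_weights`), `support` (logical per
#'   gene), and `trace` (per-epoch loss and sparsity log).
#' @export
train_double_descent <- function(dataset, config, seed = config$seed,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  X <- as.matrix(dataset$X)
  Y <- as.integer(dataset$Y)
  if (length(unique(Y)) < 2L) {
    stopf("train_double_descent: training data contains a single class")
  }
  init <- ssae_init(ncol(X), config$hidden_dim, seed = seed)

  phase1 <- run_descent(init, X, Y, config, config$epochs_phase1,
                        "phase1", seed, engine = engine)
  support <- feature_support(phase1$weights$W1)

  rewound <- init
  rewound$W1[!support, ] <- 0
  rewound$W1 <- project_l11_bilevel(rewound$W1, config$eta)
  phase2 <- run_descent(rewound, X, Y, config, config$epochs_phase2,
                        "phase2", seed, support_mask = support,
                        engine = engine)

  list(weights = phase2$weights, support = support,
       trace = rbind(phase1$trace, phase2$trace))
}

stratified_folds <- function(Y, n_folds, seed) {
  counts <- table(factor(Y, levels = c(0L, 1L)))
  if (any(counts < n_folds)) {
    stopf(paste0("insufficient cells: class with %d cells cannot be split ",
                 "into %d stratified folds"), min(counts), n_folds)
  }
  fold <- integer(length(Y))
  set.seed(derive_seed(seed, "folds"))
  for (cls in c(0L, 1L)) {
    idx <- which(Y == cls)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Stratified cross-validated evaluation
#'
#' For every (fold, seed) pair a model is trained from scratch with
#' [train_double_descent()] on the other folds and evaluated on the
#' held-out fold. Fold assignment is re-drawn for every seed (the
#' train/validation split is random every time), deterministically from
#' the run seed.
#'
#' @param dataset A `labeled_dataset`; each class needs at least `n_folds`
#'   cells.
#' @param config A [train_config()].
#' @return A `fit_report`: list with `accuracy_mean`, `accuracy_sd`,
#'   `f1_mean`, `f1_sd`, `selected_fraction_mean`, `records` (one row per
#'   fold x seed), and `oof_scores` (n x n_seeds matrix of out-of-fold
#'   class-1 probabilities, consumed by the cell-selection stage).
#' @export
crossvalidate <- function(dataset, config) {
  Y <- as.integer(dataset$Y)
  n <- length(Y)
  records <- list()
  oof <- matrix(NA_real_, n, config$n_seeds)
  for (s in seq_len(config$n_seeds)) {
    seed_s <- derive_seed(config$seed, "cvseed", s)
    fold <- stratified_folds(Y, config$n_folds, derive_seed(seed_s, "split"))
    for (f in seq_len(config$n_folds)) {
      tr <- fold != f
      ds_tr <- dataset
      ds_tr$X <- dataset$X[tr, , drop = FALSE]
      ds_tr$Y <- Y[tr]
      fit <- train_double_descent(ds_tr, config,
                                  seed = derive_seed(seed_s, "fold", f))
      out <- ssae_forward(fit$weights, dataset$X[!tr, , drop = FALSE])
      perf <- accuracy_f1(out$scores, Y[!tr])
      oof[!tr, s] <- out$scores[, 2L]
      records[[length(records) + 1L]] <- data.frame(
        fold = f, seed = s, accuracy = perf[["accuracy"]],
        f1 = perf[["f1"]],
        selected_fraction = selected_feature_fraction(fit$weights$W1))
    }
  }
  records <- do.call(rbind, records)
  structure(list(
    accuracy_mean = mean(records$accuracy),
    accuracy_sd = stats::sd(records$accuracy),
    f1_mean = mean(records$f1),
    f1_sd = stats::sd(records$f1),
    selected_fraction_mean = mean(records$selected_fraction),
    records = records,
    oof_scores = oof), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(
    "<fit_report> accuracy %.3f +/- %.3f | F1 %.3f +/- %.3f | %.1f%% genes\n",
    x$accuracy_mean, x$accuracy_sd, x$f1_mean, x$f1_sd,
    100 * x$selected_fraction_mean))
  invisible(x)
}

#' Golden-section search of the sparsity radius
#'
#' Maximizes an objective (by default the cross-validated mean accuracy as
#' a function of eta, which is concave in practice) by golden-section
#' search over `[eta_low, eta_high]`.
#'
#' @param dataset A `labeled_dataset` (ignored when `objective` is given).
#' @param config A [train_config()]; its `eta` is overridden per
#'   evaluation.
#' @param eta_low,eta_high Search bracket, `0 < eta_low < eta_high`.
#' @param max_evals Maximum number of objective evaluations (default 20).
#' @param objective Optional function `f(eta) -> scalar` replacing the
#'   cross-validation objective (used for testing and custom criteria).
#' @return List with `eta` (the best evaluated point), `value`, and
#'   `trace` (data.frame of every `(eta, value)` evaluated, in order).
#' @export
tune_eta <- function(dataset, config, eta_low, eta_high, max_evals = 20L,
                     objective = NULL) {
  if (eta_low < 0 || eta_low >= eta_high) {
    stopf("tune_eta: need 0 <= eta_low < eta_high")
  }
  if (is.null(objective)) {
    objective <- function(eta) {
      cfg <- config
      cfg$eta <- eta
      crossvalidate(dataset, cfg)$accuracy_mean
    }
  }
  evals <- data.frame(eta = numeric(0), value = numeric(0))
  f <- function(eta) {
    v <- objective(eta)
    if (!is.finite(v)) stopf("tune_eta: non-finite objective at eta=%g", eta)
    evals[nrow(evals) + 1L, ] <<- c(eta, v)
    v
  }
  gr <- (sqrt(5) - 1) / 2
  a <- eta_low; b <- eta_high
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (nrow(evals) < max_evals) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  best <- which.max(evals$value)
  list(eta = evals$eta[best], value = evals$value[best], trace = evals)
}
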