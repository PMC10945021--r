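## The SSAE network: a symmetric fully connected autoencoder
##   encoder: d -> h (ReLU) -> k = 2 latent
##   decoder: 2 -> h (ReLU) -> d reconstruction
## with a softmax classification head read directly off the two latent
## coordinates. The first encoder layer (genes -> hidden) carries the l1,1
## sparsity constraint and defines gene selection.

#' Initialize SSAE weights
#'
#' Glorot-uniform initialization of the four layers of the symmetric
#' autoencoder. The latent dimension is fixed at k = 2, one coordinate per
#' class; encoder and decoder mirror each other's shapes but are untied.
#'
#' @param n_genes Number of input genes d.
#' @param hidden_dim Width h of the single hidden layer (default 100).
#' @param seed Integer seed for reproducible initialization.
#' @return An object of class `ssae_weights`: list with matrices `W1`
#'   (d x h), `W2` (h x 2), `W3` (2 x h), `W4` (h x d) and bias vectors
#'   `b1`, `b2`, `b3`, `b4`.
#' @export
ssae_init <- function(n_genes, hidden_dim = 100L, seed = 1L) {
  stopifnot(n_genes >= 1, hidden_dim >= 1)
  set.seed(derive_seed(seed, "init"))
  glorot <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  w <- list(
    W1 = glorot(n_genes, hidden_dim), b1 = numeric(hidden_dim),
    W2 = glorot(hidden_dim, 2L),      b2 = numeric(2L),
    W3 = glorot(2L, hidden_dim),      b3 = numeric(hidden_dim),
    W4 = glorot(hidden_dim, n_genes), b4 = numeric(n_genes)
  )
  structure(w, class = "ssae_weights")
}

#' Forward pass of the SSAE
#'
#' @param weights An `ssae_weights` object.
#' @param X Numeric n x d matrix (cells in rows, genes in columns).
#' @return List with `Z` (n x 2 latent coordinates), `X_hat` (n x d
#'   reconstruction), `scores` (n x 2 softmax class probabilities), and the
#'   hidden activations `H1`, `H2` needed for backpropagation.
#' @export
ssae_forward <- function(weights, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != nrow(weights$W1)) {
    stopf("ssae_forward: X has %d columns but the model expects %d genes",
          ncol(X), nrow(weights$W1))
  }
  H1 <- pmax(X %*% weights$W1 + rep(weights$b1, each = nrow(X)), 0)
  Z <- H1 %*% weights$W2 + rep(weights$b2, each = nrow(X))
  H2 <- pmax(Z %*% weights$W3 + rep(weights$b3, each = nrow(X)), 0)
  X_hat <- H2 %*% weights$W4 + rep(weights$b4, each = nrow(X))
  list(Z = Z, X_hat = X_hat, scores = softmax_scores(Z), H1 = H1, H2 = H2)
}

#' Row-wise softmax with max-subtraction stabilization
#'
#' @param Z Numeric n x k matrix of logits.
#' @return n x k matrix of probabilities; each row sums to 1.
#' @examples
#' softmax_scores(rbind(c(0, 0)))       # 0.5 0.5
#' softmax_scores(rbind(c(log(3), 0)))  # 0.75 0.25
#' @export
softmax_scores <- function(Z) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  if (anyNA(Z) || any(!is.finite(Z))) stopf("softmax_scores: non-finite logits")
  E <- exp(Z - apply(Z, 1L, max))
  E / rowSums(E)
}

#' Huber (smooth-l1) reconstruction loss
#'
#' Elementwise `0.5 r^2 / delta` for `|r| <= delta`, else
#' `|r| - 0.5 delta`, averaged over all entries. Quadratic near zero,
#' linear in the tails, hence robust to the occasional huge UMI count.
#'
#' @param residual Numeric matrix (or vector) of reconstruction residuals.
#' @param delta Positive transition point between the branches.
#' @return Scalar mean loss.
#' @export
huber_loss <- function(residual, delta = 1) {
  stopifnot(is.numeric(residual), delta > 0)
  a <- abs(residual)
  q <- pmin(a, delta)                  # branch-free: q*(a - q/2)/delta
  mean(q * (a - q / 2)) / delta
}

## Weighted cross-entropy of softmax scores against binary labels.
## class_weights is a length-2 vector (weight for class 0, class 1);
## the loss is the weighted mean of -log p_correct.
cross_entropy <- function(scores, Y, class_weights = c(1, 1)) {
  p <- scores[cbind(seq_along(Y), Y + 1L)]
  w <- class_weights[Y + 1L]
  sum(w * -log(pmax(p, 1e-12))) / sum(w)
}

#' Joint SSAE loss
#'
#' `total = CE(scores, Y) + lambda * Huber(X_hat - X, delta)`: the
#' cross-entropy classification term plus the weighted Huber reconstruction
#' term of the supervised autoencoder objective.
#'
#' @param out Forward-pass output from [ssae_forward()].
#' @param X Input matrix the model was run on.
#' @param Y Integer 0/1 labels (0 = control, 1 = targeted/perturbed).
#' @param lambda Nonnegative reconstruction trade-off (default 1).
#' @param delta Huber transition point (default 1).
#' @param class_weights Length-2 vector of class weights for the CE term.
#' @return List with `total`, `ce`, `reconstruction`.
#' @export
ssae_loss <- function(out, X, Y, lambda = 1, delta = 1,
                      class_weights = c(1, 1)) {
  if (lambda < 0) stopf("ssae_loss: lambda must be nonnegative")
  ce <- cross_entropy(out$scores, Y, class_weights)
  rec <- huber_loss(out$X_hat - X, delta)
  list(total = ce + lambda * rec, ce = ce, reconstruction = rec)
}

#' Accuracy and F1 of softmax predictions
#'
#' Predictions are the argmax class. F1 is computed for the perturbed
#' class (label 1) and defined as 0 when positives exist but none are
#' predicted.
#'
#' @param scores n x 2 probability matrix.
#' @param Y Integer 0/1 labels.
#' @return Named vector `c(accuracy = ..., f1 = ...)`, both fractions.
#' @export
accuracy_f1 <- function(scores, Y) {
  pred <- as.integer(scores[, 2L] > scores[, 1L])
  acc <- mean(pred == Y)
  tp <- sum(pred == 1L & Y == 1L)
  fp <- sum(pred == 1L & Y == 0L)
  fn <- sum(pred == 0L & Y == 1L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = acc, f1 = f1)
}

## Analytic gradients of the joint loss with respect to all weights.
## Returns a list matching the layout of ssae_weights. Derivation is plain
## backpropagation through the two ReLU layers; the CE and (scaled) Huber
## terms both feed into the latent Z, the Huber term through the decoder.
ssae_gradients <- function(weights, X, Y, lambda = 1, delta = 1,
                           class_weights = c(1, 1), out = NULL) {
  n <- nrow(X)
  if (is.null(out)) out <- ssae_forward(weights, X)
  w <- class_weights[Y + 1L]
  onehot <- cbind(1 - Y, Y)
  dZ_ce <- (out$scores - onehot) * (w / sum(w))

  R <- out$X_hat - X
  # Huber derivative is clamp(R / delta, -1, 1)
  dXhat <- pmax(pmin(R / delta, 1), -1) * (lambda / length(R))

  dW4 <- crossprod(out$H2, dXhat)
  db4 <- colSums(dXhat)
  dH2 <- tcrossprod(dXhat, weights$W4) * (out$H2 > 0)
  dW3 <- crossprod(out$Z, dH2)
  db3 <- colSums(dH2)
  dZ <- dZ_ce + tcrossprod(dH2, weights$W3)

  dW2 <- crossprod(out$H1, dZ)
  db2 <- colSums(dZ)
  dH1 <- tcrossprod(dZ, weights$W2) * (out$H1 > 0)
  dW1 <- crossprod(X, dH1)
  db1 <- colSums(dH1)

  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       W3 = dW3, b3 = db3, W4 = dW4, b4 = db4)
}
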