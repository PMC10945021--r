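## Feature attribution for the trained SSAE, rank aggregation across
## seeds, fold-change direction annotation, and stability flagging of the
## perturbation signature.

## Gradient of the class-1 latent logit with respect to the input, for a
## batch of points P (rows). f(x) = (ReLU(x W1 + b1) W2 + b2)[2]; since the
## network past the input is piecewise linear, the gradient at P is
## W1 %*% (relu_mask * W2[, 2]) row by row.
logit1_gradient <- function(weights, P) {
  H <- P %*% weights$W1 + rep(weights$b1, each = nrow(P))
  M <- (H > 0) * rep(weights$W2[, 2L], each = nrow(P))
  tcrossprod(M, weights$W1)
}

## Class-1 logit values for a batch.
logit1_value <- function(weights, P) {
  H <- pmax(P %*% weights$W1 + rep(weights$b1, each = nrow(P)), 0)
  as.vector(H %*% weights$W2[, 2L] + weights$b2[2L])
}

#' Shapley-style per-gene attribution of the class-1 logit
#'
#' Sampled-baseline path integration (expected gradients): for every
#' evaluation cell the gradient of the class-1 logit is integrated along
#' straight paths from control baselines drawn from `baseline_pool` to the
#' cell, and multiplied by the input difference. The per-gene attribution
#' is the mean absolute attribution over evaluation cells. Genes with a
#' zeroed first-layer row necessarily receive exactly 0.
#'
#' @param weights Trained `ssae_weights`.
#' @param X_eval Matrix of evaluation cells (rows), typically the
#'   perturbed class.
#' @param baseline_pool Matrix of baseline cells, typically controls.
#' @param n_baseline_samples Number of baselines drawn (with replacement
#'   when the pool is smaller) from the pool.
#' @param seed Seed for the baseline draw.
#' @param n_steps Riemann (midpoint) steps per path (default 10).
#' @return Named numeric vector of nonnegative per-gene attributions.
#' @export
attribute_features <- function(weights, X_eval, baseline_pool,
                               n_baseline_samples = 10L, seed = 1L,
                               n_steps = 10L) {
  X_eval <- as.matrix(X_eval)
  baseline_pool <- as.matrix(baseline_pool)
  if (nrow(baseline_pool) == 0) {
    stopf("attribute_features: empty baseline pool")
  }
  set.seed(derive_seed(seed, "baselines"))
  bidx <- sample.int(nrow(baseline_pool), n_baseline_samples,
                     replace = nrow(baseline_pool) < n_baseline_samples)
  n <- nrow(X_eval)
  total <- matrix(0, n, ncol(X_eval))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  for (bi in bidx) {
    B <- matrix(baseline_pool[bi, ], n, ncol(X_eval), byrow = TRUE)
    D <- X_eval - B
    G <- matrix(0, n, ncol(X_eval))
    for (a in alphas) {
      G <- G + logit1_gradient(weights, B + a * D)
    }
    total <- total + D * (G / n_steps)
  }
  per_cell <- total / length(bidx)
  attr <- colMeans(abs(per_cell))
  names(attr) <- colnames(X_eval)
  attr
}

## Per-cell signed attributions plus endpoint logits; used to check the
## path-integration completeness property (sum of attributions equals the
## logit difference when the path stays in one ReLU region).
attribute_cells_signed <- function(weights, X_eval, baseline, n_steps = 10L) {
  X_eval <- as.matrix(X_eval)
  n <- nrow(X_eval)
  B <- matrix(baseline, n, ncol(X_eval), byrow = TRUE)
  D <- X_eval - B
  G <- matrix(0, n, ncol(X_eval))
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  for (a in alphas) G <- G + logit1_gradient(weights, B + a * D)
  list(attributions = D * (G / n_steps),
       logit_eval = logit1_value(weights, X_eval),
       logit_baseline = logit1_value(weights, matrix(baseline, 1L)))
}

## Rank genes by decreasing attribution within the selected support;
## deselected genes get the worst rank d. Ties broken by gene order.
attribution_ranks <- function(attr, support) {
  d <- length(attr)
  r <- rep(d, d)
  sel <- which(support)
  if (length(sel)) {
    r[sel][order(attr[sel], decreasing = TRUE)] <- seq_along(sel)
  }
  names(r) <- names(attr)
  r
}

#' Aggregate gene ranks across runs
#'
#' @param rankings List (length >= 2) of equal-length rank vectors over the
#'   same gene universe, one per seed/run; genes not selected in a run
#'   carry the worst rank d there.
#' @return data.frame with `mean_rank` and `sd_rank` per gene.
#' @export
aggregate_ranks <- function(rankings) {
  if (length(rankings) < 2L) {
    stopf("aggregate_ranks: need at least two rankings for a standard deviation")
  }
  lens <- vapply(rankings, length, 1L)
  if (length(unique(lens)) != 1L) {
    stopf("aggregate_ranks: rankings cover different gene universes")
  }
  nms <- lapply(rankings, names)
  if (!all(vapply(nms, identical, TRUE, y = nms[[1L]]))) {
    stopf("aggregate_ranks: rankings cover different gene universes")
  }
  R <- do.call(cbind, rankings)
  data.frame(gene = rownames(R) %||% as.character(seq_len(nrow(R))),
             mean_rank = rowMeans(R),
             sd_rank = apply(R, 1L, stats::sd),
             stringsAsFactors = FALSE)
}

#' Per-gene log2 fold change, perturbed vs control
#'
#' Counts are first normalized per cell to the mean library size of the
#' dataset; the fold change is
#' `log2((mean_perturbed + eps) / (mean_control + eps))`.
#'
#' @param dataset The round-1 `labeled_dataset`.
#' @param perturbed_indices Row indices of the perturbed cells.
#' @param pseudocount eps added to both means (default 1).
#' @return Named numeric vector, one signed value per gene; positive means
#'   up-regulated in perturbed cells.
#' @export
compute_log2fc <- function(dataset, perturbed_indices, pseudocount = 1) {
  if (length(perturbed_indices) == 0) stopf("compute_log2fc: empty perturbed group")
  ctrl <- which(dataset$Y == 0L)
  if (length(ctrl) == 0) stopf("compute_log2fc: empty control group")
  X <- as.matrix(dataset$X)
  lib <- rowSums(X)
  lib[lib == 0] <- 1
  Xn <- X / lib * mean(lib)
  mp <- colMeans(Xn[perturbed_indices, , drop = FALSE])
  mc <- colMeans(Xn[ctrl, , drop = FALSE])
  out <- log2((mp + pseudocount) / (mc + pseudocount))
  names(out) <- dataset$gene_ids
  out
}

#' Assemble the ranked perturbation signature table
#'
#' Genes are ordered by mean rank across runs (ties broken by higher mean
#' attribution, then gene id); the top `top_n` ever-selected genes are
#' kept. A gene is flagged `stable` when its rank standard deviation is at
#' most `sd_threshold` and its fold change is material
#' (`|log2fc| >= min_abs_lfc`); direction is the sign of its log2 fold
#' change.
#'
#' @param attributions List of per-run attribution vectors.
#' @param rankings List of matching per-run rank vectors.
#' @param log2fc Per-gene log2 fold changes from [compute_log2fc()].
#' @param gene_ids Gene universe (defaults to `names(log2fc)`).
#' @param top_n Signature length (default 20).
#' @param sd_threshold Rank-stability cut-off on `sd_rank` (default 3): the
#'   gene occupies essentially the same rank in every repetition. Relative
#'   cut-offs (a fraction of the gene-universe size) are far too lenient:
#'   on a 1000-gene null screen, genes whose rank fluctuates by dozens of
#'   positions would still be called stable.
#' @param min_abs_lfc Effect-size condition on the `stable` flag (default
#'   0.5): a stable signature gene must also be materially regulated,
#'   `|log2fc| >= min_abs_lfc`. With only a few repetitions, rank spread
#'   alone cannot distinguish a real signature gene from a noise gene that
#'   happens to hold its rank; the fold-change condition removes the
#'   latter, whose effect sizes hover near zero.
#' @return A `signature_table` data.frame with columns gene, attribution,
#'   mean_rank, sd_rank, log2fc, direction, stable.
#' @export
build_signature <- function(attributions, rankings, log2fc,
                            gene_ids = names(log2fc), top_n = 20L,
                            sd_threshold = 3, min_abs_lfc = 0.5) {
  agg <- aggregate_ranks(rankings)
  d <- nrow(agg)
  attr_mean <- rowMeans(do.call(cbind, attributions))
  ever_selected <- agg$mean_rank < d
  n_avail <- sum(ever_selected)
  if (n_avail == 0) stopf("build_signature: no gene was ever selected")
  if (top_n > n_avail) {
    warnf("build_signature: only %d genes ever selected (top_n = %d)",
          n_avail, top_n)
    top_n <- n_avail
  }
  df <- data.frame(gene = gene_ids,
                   attribution = unname(attr_mean),
                   mean_rank = agg$mean_rank,
                   sd_rank = agg$sd_rank,
                   log2fc = unname(log2fc[gene_ids]),
                   stringsAsFactors = FALSE)
  df <- df[ever_selected, , drop = FALSE]
  df <- df[order(df$mean_rank, -df$attribution, df$gene), , drop = FALSE]
  df <- df[seq_len(top_n), , drop = FALSE]
  df$direction <- ifelse(df$log2fc >= 0, "up", "down")
  df$stable <- df$sd_rank <= sd_threshold & abs(df$log2fc) >= min_abs_lfc
  rownames(df) <- NULL
  class(df) <- c("signature_table", "data.frame")
  df
}
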