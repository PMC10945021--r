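## The two-round perturbed-cell selection procedure: a first
## cross-validated run assigns every cell a softmax perturbation score;
## targeted cells scoring above 0.5 are kept as "perturbed" and re-fit
## against an equal number of randomly drawn control cells in a second,
## class-balanced round that yields the final signature.

#' Per-cell perturbation scores
#'
#' Each cell's score is its out-of-fold class-1 softmax probability
#' (predicted by models that never saw the cell during training), averaged
#' over the initialization seeds.
#'
#' @param dataset A `labeled_dataset`.
#' @param config A [train_config()].
#' @param report Optional precomputed [crossvalidate()] report to reuse.
#' @return A `perturbation_scores` object: list with `score`
#'   (seed-averaged, per cell), `per_seed` (n x n_seeds matrix),
#'   `barcodes`, `Y`.
#' @export
score_cells <- function(dataset, config, report = NULL) {
  if (is.null(report)) report <- crossvalidate(dataset, config)
  structure(list(score = rowMeans(report$oof_scores),
                 per_seed = report$oof_scores,
                 barcodes = dataset$barcodes,
                 Y = as.integer(dataset$Y)),
            class = "perturbation_scores")
}

#' Split targeted cells into perturbed / non-perturbed
#'
#' Targeted cells with a score strictly above `threshold` are classified
#' as perturbed; all others (including cells scoring exactly at the
#' threshold) as non-perturbed. Control cells are never part of either
#' subset regardless of their score.
#'
#' @param scores A `perturbation_scores` object.
#' @param dataset The matching `labeled_dataset`.
#' @param threshold Score cut-off (default 0.5).
#' @return List with `perturbed_indices`, `nonperturbed_indices` (indices
#'   into the dataset rows, targeted cells only), and `pct_perturbed`
#'   (fraction of targeted cells classified perturbed).
#' @export
select_perturbed <- function(scores, dataset, threshold = 0.5) {
  stopifnot(inherits(scores, "perturbation_scores"))
  if (length(scores$score) != length(dataset$Y)) {
    stopf("select_perturbed: scores cover %d cells but dataset has %d",
          length(scores$score), length(dataset$Y))
  }
  targ <- which(dataset$Y == 1L)
  pert <- targ[scores$score[targ] > threshold]
  list(perturbed_indices = pert,
       nonperturbed_indices = setdiff(targ, pert),
       pct_perturbed = length(pert) / length(targ))
}

#' Build the balanced second-round dataset
#'
#' All perturbed cells (label 1) plus an equal number of control cells
#' sampled without replacement (label 0). If fewer controls exist than
#' perturbed cells, all controls are used and a warning is raised.
#'
#' @param dataset The round-1 `labeled_dataset`.
#' @param perturbed_indices Row indices of the perturbed cells.
#' @param seed Seed for the control subsample.
#' @return A class-balanced `labeled_dataset`.
#' @export
build_second_round <- function(dataset, perturbed_indices, seed) {
  if (length(perturbed_indices) < 1L) {
    stopf("build_second_round: no perturbed cells")
  }
  if (any(dataset$Y[perturbed_indices] != 1L)) {
    stopf("build_second_round: perturbed indices must be targeted cells")
  }
  ctrl <- which(dataset$Y == 0L)
  n_pert <- length(perturbed_indices)
  if (length(ctrl) < n_pert) {
    warnf(paste0("build_second_round: only %d controls for %d perturbed ",
                 "cells; using all controls (classes not exactly balanced)"),
          length(ctrl), n_pert)
    keep_ctrl <- ctrl
  } else {
    set.seed(derive_seed(seed, "round2", "controls"))
    keep_ctrl <- sort(sample(ctrl, n_pert))
  }
  idx <- c(keep_ctrl, perturbed_indices)
  structure(list(X = dataset$X[idx, , drop = FALSE],
                 Y = c(rep(0L, length(keep_ctrl)), rep(1L, n_pert)),
                 gene_ids = dataset$gene_ids,
                 barcodes = dataset$barcodes[idx],
                 target_gene = dataset$target_gene,
                 condition = dataset$condition),
            class = "labeled_dataset")
}

#' Run the full two-round analysis for one (target, condition) dataset
#'
#' Round 1: cross-validated training on controls vs all targeted cells,
#' out-of-fold perturbation scores, strict >0.5 split of the targeted
#' cells. If fewer than `min_cells_per_class` cells are classified as
#' perturbed the second round is skipped (there are too few cells for a
#' stratified 4-fold cross-validation to be meaningful) and only the
#' round-1 report is returned. Otherwise the second round is repeated once
#' per seed: each repetition selects the perturbed cells from that seed's
#' own out-of-fold scores (falling back to the seed-averaged selection if
#' a single seed passes too few cells), draws a fresh balanced control
#' subsample, re-fits, and ranks genes by attribution. The signature's
#' rank mean and spread are computed across these repetitions, so the
#' stability flag reflects robustness to every stochastic element of the
#' pipeline, not just to re-initialization on one fixed cell split.
#'
#' @param dataset A `labeled_dataset`.
#' @param config A [train_config()].
#' @param min_cells_per_class Minimum number of perturbed cells required
#'   to attempt the second round (default 40).
#' @param threshold Perturbation-score cut-off (default 0.5).
#' @param top_n Signature length (default 20).
#' @param sd_threshold Rank-stability cut-off passed to
#'   [build_signature()] (default 3).
#' @return A `two_step_result`: list with `first_report`, `scores`,
#'   `perturbed_indices`, `pct_perturbed`, `skipped_second_round`,
#'   `skip_reason`, and (when round 2 ran) `second_report` and
#'   `signature`.
#' @export
run_two_step <- function(dataset, config, min_cells_per_class = 40L,
                         threshold = 0.5, top_n = 20L,
                         sd_threshold = NULL) {
  first_report <- crossvalidate(dataset, config)
  scores <- score_cells(dataset, config, report = first_report)
  sel <- select_perturbed(scores, dataset, threshold)

  res <- list(first_report = first_report, scores = scores,
              perturbed_indices = sel$perturbed_indices,
              pct_perturbed = sel$pct_perturbed,
              second_report = NULL, signature = NULL,
              skipped_second_round = FALSE, skip_reason = NA_character_)
  class(res) <- "two_step_result"

  n_pert <- length(sel$perturbed_indices)
  if (n_pert < min_cells_per_class) {
    res$skipped_second_round <- TRUE
    res$skip_reason <- sprintf(
      paste0("only %d perturbed cells (< %d): too few for the %d-fold ",
             "cross-validation of the second round; accuracy reported ",
             "without cell selection"),
      n_pert, min_cells_per_class, config$n_folds)
    return(res)
  }

  ## Round 2: the procedure is repeated once per seed, and the rank
  ## spread across these repetitions measures the robustness of the
  ## signature. Each repetition re-selects the perturbed cells from that
  ## seed's own out-of-fold scores (falling back to the seed-averaged
  ## selection if a single seed selects too few cells) and draws a fresh
  ## balanced control subsample, so everything stochastic about the
  ## pipeline — scores, cell selection, controls, initialization — varies
  ## between repetitions. A gene is only ever called stable if its rank
  ## survives all of that.
  targ <- which(dataset$Y == 1L)
  second_records <- list()
  rankings <- list()
  attributions <- list()
  for (s in seq_len(config$n_seeds)) {
    seed_s <- derive_seed(config$seed, "round2seed", s)
    pert_s <- targ[scores$per_seed[targ, s] > threshold]
    if (length(pert_s) < min_cells_per_class) pert_s <- sel$perturbed_indices
    ds2 <- build_second_round(dataset, pert_s, seed = seed_s)
    cfg2 <- config
    cfg2$seed <- seed_s
    cfg2$n_seeds <- 1L
    rep2 <- crossvalidate(ds2, cfg2)
    second_records[[s]] <- transform(rep2$records, seed = s)

    fit <- train_double_descent(ds2, cfg2, seed = derive_seed(seed_s, "full"))
    attr_s <- attribute_features(
      fit$weights,
      X_eval = ds2$X[ds2$Y == 1L, , drop = FALSE],
      baseline_pool = ds2$X[ds2$Y == 0L, , drop = FALSE],
      n_baseline_samples = 10L,
      seed = derive_seed(seed_s, "shap"))
    attributions[[s]] <- attr_s
    rankings[[s]] <- attribution_ranks(attr_s, fit$support)
  }
  records <- do.call(rbind, second_records)
  res$second_report <- structure(list(
    accuracy_mean = mean(records$accuracy),
    accuracy_sd = stats::sd(records$accuracy),
    f1_mean = mean(records$f1),
    f1_sd = stats::sd(records$f1),
    selected_fraction_mean = mean(records$selected_fraction),
    records = records, oof_scores = NULL), class = "fit_report")

  lfc <- compute_log2fc(dataset, sel$perturbed_indices)
  res$signature <- build_signature(
    attributions = attributions, rankings = rankings, log2fc = lfc,
    gene_ids = dataset$gene_ids, top_n = top_n,
    sd_threshold = sd_threshold %||% 3)
  res
}

#' @export
print.two_step_result <- function(x, ...) {
  cat(sprintf("<two_step_result> round 1 accuracy %.3f | %.1f%% perturbed\n",
              x$first_report$accuracy_mean, 100 * x$pct_perturbed))
  if (x$skipped_second_round) {
    cat("  second round skipped:", x$skip_reason, "\n")
  } else {
    cat(sprintf("  round 2 accuracy %.3f | signature of %d genes\n",
                x$second_report$accuracy_mean, nrow(x$signature)))
  }
  invisible(x)
}

#' Export per-cell scores as a data.frame
#'
#' @param scores A `perturbation_scores` object.
#' @param perturbed_indices Indices flagged perturbed (optional).
#' @return data.frame with barcode, label, score, perturbed flag.
#' @export
scores_table <- function(scores, perturbed_indices = integer(0)) {
  data.frame(barcode = scores$barcodes,
             label = scores$Y,
             score = scores$score,
             perturbed = seq_along(scores$score) %in% perturbed_indices,
             stringsAsFactors = FALSE)
}
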