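## CROP-seq-like simulator with known ground truth. Counts are negative
## binomial in the mean/dispersion parameterization Var = mu + mu^2/theta
## (the standard scRNA-seq convention). Three cell populations are
## generated: negative-control cells; gRNA-targeted cells, all of which
## carry a knock-down of the target gene with per-cell efficiency (the
## gRNA is present in every targeted cell); and, among the targeted cells,
## a "perturbed" fraction that additionally expresses a planted downstream
## log-fold-change signature. This mirrors screens where the target
## knock-down is near-universal but its downstream transcriptomic
## consequence has incomplete penetrance.

#' Simulation configuration
#'
#' @param n_control Number of negative-control cells.
#' @param n_targeted Number of gRNA-targeted cells.
#' @param n_genes Number of genes d.
#' @param n_signature Number of planted signature genes.
#' @param frac_perturbed Fraction in (0, 1] of targeted cells in which the
#'   downstream signature is actually expressed (knockdown penetrance).
#' @param signature_lfc Signed log2 fold changes of the signature genes in
#'   perturbed cells; a scalar is expanded to alternating +/- values.
#' @param knockdown_factor Multiplicative factor in (0, 1) applied to the
#'   target gene's mean in targeted cells (0.1 means a 90 percent
#'   knock-down).
#' @param knockdown_sd Per-cell spread of the knock-down efficiency; each
#'   targeted cell draws its factor from a normal truncated to (0, 1)
#'   centered at `knockdown_factor`.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters for the
#'   baseline gene means (natural log scale).
#' @param target_log_mean Natural-log mean expression of the target gene;
#'   defaults to `log(0.5)`, a lowly expressed transcript as is typical of
#'   lncRNA CRISPRi targets, so the knock-down is a weak per-cell signal
#'   that is nonetheless consistent across every targeted cell.
#' @param signature_min_mean Signature genes are drawn among genes whose
#'   baseline mean is at least this (default 3): observable perturbation
#'   signatures are made of reasonably abundant transcripts.
#' @param dispersion Negative-binomial shape theta (> 0); smaller is
#'   noisier.
#' @param condition Condition label written into the annotations.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_control = 300L, n_targeted = 300L,
                       n_genes = 1000L, n_signature = 10L,
                       frac_perturbed = 0.7, signature_lfc = 1.5,
                       knockdown_factor = 0.1, knockdown_sd = 0.05,
                       baseline_log_mean = 0, baseline_log_sd = 1.2,
                       target_log_mean = log(0.5), signature_min_mean = 3,
                       dispersion = 2, condition = "normoxia", seed = 1L) {
  cfg <- list(n_control = as.integer(n_control),
              n_targeted = as.integer(n_targeted),
              n_genes = as.integer(n_genes),
              n_signature = as.integer(n_signature),
              frac_perturbed = frac_perturbed,
              signature_lfc = signature_lfc,
              knockdown_factor = knockdown_factor,
              knockdown_sd = knockdown_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              target_log_mean = target_log_mean,
              signature_min_mean = signature_min_mean,
              dispersion = dispersion,
              condition = as.character(condition),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_control < 1 || cfg$n_targeted < 1) {
    stopf("sim_config: need at least one cell per class")
  }
  if (cfg$n_signature >= cfg$n_genes) {
    stopf("sim_config: n_signature must be smaller than n_genes")
  }
  if (cfg$frac_perturbed <= 0 || cfg$frac_perturbed > 1) {
    stopf("sim_config: frac_perturbed must be in (0, 1]")
  }
  if (cfg$knockdown_factor <= 0 || cfg$knockdown_factor >= 1) {
    stopf("sim_config: knockdown_factor must be in (0, 1)")
  }
  if (cfg$dispersion <= 0) stopf("sim_config: dispersion must be > 0")
  if (cfg$knockdown_sd < 0) stopf("sim_config: knockdown_sd must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("read_sim_config: no file '%s'", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown)) {
    stopf("read_sim_config: unknown field(s): %s",
          paste(unknown, collapse = ", "))
  }
  do.call(sim_config, vals)
}

## Truncated-normal draw on (lo, hi) via inverse-CDF; exact, no rejection.
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

## Shared machinery for simulate_cropseq / simulate_null.
simulate_core <- function(config, null_model) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "simulate"))
  d <- config$n_genes
  n0 <- config$n_control
  n1 <- config$n_targeted

  mu <- stats::rlnorm(d, config$baseline_log_mean, config$baseline_log_sd)
  target_idx <- sample.int(d, 1L)
  mu[target_idx] <- exp(config$target_log_mean)

  if (null_model) {
    sig_idx <- integer(0)
    lfc <- numeric(0)
    perturbed <- rep(FALSE, n1)
    efficiency <- rep(1, n1)
  } else {
    lfc <- config$signature_lfc
    if (length(lfc) == 1L) {
      lfc <- rep_len(c(1, -1), config$n_signature) * abs(lfc)
    }
    if (length(lfc) != config$n_signature) {
      stopf("simulate_cropseq: signature_lfc must have length 1 or n_signature")
    }
    # signature genes drawn among well-expressed genes: detected
    # perturbation signatures are made of abundant transcripts, and a fold
    # change on a barely-detected gene is not an observable signature
    eligible <- setdiff(which(mu >= config$signature_min_mean), target_idx)
    if (length(eligible) < config$n_signature) {
      eligible <- setdiff(order(mu, decreasing = TRUE), target_idx)
    }
    sig_idx <- sort(sample(eligible, config$n_signature))
    perturbed <- stats::runif(n1) < config$frac_perturbed
    efficiency <- rtruncnorm01(n1, config$knockdown_factor,
                               config$knockdown_sd)
  }

  M <- matrix(mu, nrow = n0 + n1, ncol = d, byrow = TRUE)
  targ_rows <- n0 + seq_len(n1)
  if (!null_model) {
    # knock-down in every targeted cell (the gRNA is always present)
    M[targ_rows, target_idx] <- mu[target_idx] * efficiency
    # downstream signature only in the perturbed subset
    pert_rows <- targ_rows[perturbed]
    if (length(pert_rows) && length(sig_idx)) {
      M[pert_rows, sig_idx] <-
        M[pert_rows, sig_idx, drop = FALSE] *
        matrix(2^lfc, length(pert_rows), length(sig_idx), byrow = TRUE)
    }
  }
  counts <- matrix(stats::rnbinom(length(M), size = config$dispersion,
                                  mu = as.vector(M)),
                   nrow = nrow(M), ncol = ncol(M))

  gene_ids <- sprintf("gene%04d", seq_len(d))
  barcodes <- sprintf("cell%05d", seq_len(n0 + n1))
  cm <- count_matrix(counts, gene_ids, barcodes)

  target_name <- gene_ids[target_idx]
  ann <- data.frame(
    barcode = barcodes,
    grna_id = c(rep("Neg-sg1", n0),
                rep(paste0(target_name, "-sg1"), n1)),
    target_gene = c(rep(CONTROL_SENTINEL, n0), rep(target_name, n1)),
    condition = config$condition,
    stringsAsFactors = FALSE)
  ann$is_control <- ann$target_gene == CONTROL_SENTINEL

  truth <- structure(list(
    perturbed_mask = perturbed,
    signature_gene_indices = sig_idx,
    signature_directions = if (length(lfc)) sign(lfc) else numeric(0),
    signature_lfc = lfc,
    target_gene_index = target_idx,
    target_gene = target_name,
    knockdown_efficiency = efficiency,
    baseline_means = mu), class = "sim_truth")

  list(counts = cm, annotations = ann, truth = truth)
}

#' Simulate a CROP-seq-like screen with planted ground truth
#'
#' Draws baseline gene means log-normally, knocks the target gene down in
#' every targeted cell with per-cell efficiency, plants the signature
#' log-fold changes only in the perturbed targeted fraction, and samples
#' negative-binomial counts. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a [count_matrix()]), `annotations`
#'   (data.frame), and `truth` (`sim_truth`: perturbed mask, signature gene
#'   indices and directions, target gene index, per-cell knock-down
#'   efficiencies, baseline means).
#' @export
simulate_cropseq <- function(config) {
  simulate_core(config, null_model = FALSE)
}

#' Simulate a null screen (no perturbation whatsoever)
#'
#' Identical generative process for "targeted" and control cells: no
#' knock-down, no planted signature. The two classes are exchangeable by
#' construction, so any classifier should perform at chance.
#'
#' @param config A [sim_config()].
#' @return Same structure as [simulate_cropseq()]; `truth$perturbed_mask`
#'   is all `FALSE` and the signature index list is empty.
#' @export
simulate_null <- function(config) {
  simulate_core(config, null_model = TRUE)
}

#' Expected mean expression gap of signature genes
#'
#' Closed-form difference in expected counts of each signature gene between
#' perturbed and control cells, `mu * (2^lfc - 1)`; used to reason about
#' effect sizes without sampling noise.
#'
#' @param config A [sim_config()].
#' @param truth The matching `sim_truth`.
#' @return Numeric vector, one expected gap per signature gene.
#' @export
expected_signature_gap <- function(config, truth) {
  mu <- truth$baseline_means[truth$signature_gene_indices]
  mu * (2^truth$signature_lfc - 1)
}
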