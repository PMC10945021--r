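# Shared fixtures: everything is generated in code, no data files.

# A small, quickly trainable screen with a strong planted effect.
small_sim <- function(seed = 42, frac_perturbed = 0.8, ...) {
  simulate_cropseq(sim_config(
    n_control = 60L, n_targeted = 60L, n_genes = 40L, n_signature = 4L,
    frac_perturbed = frac_perturbed, signature_lfc = 2.5, seed = seed, ...))
}

small_dataset <- function(seed = 42, ...) {
  sim <- small_sim(seed, ...)
  assemble_dataset(sim$counts, sim$annotations,
                   sim$truth$target_gene, "normoxia")
}

# Training config sized for unit tests (few epochs, small net).
tiny_train_config <- function(eta = 20, n_folds = 2L, n_seeds = 2L,
                              epochs_phase1 = 5L, epochs_phase2 = 5L, ...) {
  train_config(eta = eta, hidden_dim = 16L, epochs_phase1 = epochs_phase1,
               epochs_phase2 = epochs_phase2, batch_size = 32L,
               n_folds = n_folds, n_seeds = n_seeds, ...)
}

# Hand-rolled labeled dataset with fully controlled values.
manual_dataset <- function(X, Y, gene_ids = sprintf("g%02d", seq_len(ncol(X)))) {
  structure(list(X = X, Y = as.integer(Y), gene_ids = gene_ids,
                 barcodes = sprintf("bc%03d", seq_len(nrow(X))),
                 target_gene = "gT", condition = "normoxia"),
            class = "labeled_dataset")
}

# Independent l1-ball projection oracle: bisection on the soft-threshold
# level (no sorting; shares no code with the package implementation).
l1_project_bisect <- function(v, radius, iters = 200L) {
  if (sum(abs(v)) <= radius) return(v)
  lo <- 0
  hi <- max(abs(v))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (sum(pmax(abs(v) - mid, 0)) > radius) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  sign(v) * pmax(abs(v) - theta, 0)
}

# Exact Euclidean projection onto the l1,1 ball: since the l1,1 norm of a
# matrix is the l1 norm of its vectorization, this is entrywise
# soft-thresholding of vec(W) — an independent oracle for the bilevel
# operator on the instances where the two coincide.
l11_project_exact <- function(W, eta) {
  matrix(l1_project_bisect(as.vector(W), eta), nrow(W), ncol(W))
}
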