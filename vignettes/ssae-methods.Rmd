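---
title: "Sparse supervised autoencoders for CRISPRi screen analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse supervised autoencoders for CRISPRi screen analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a pooled CRISPR interference screen with single-cell transcriptomic
readout (CROP-seq), each cell carries one guide RNA and its whole
transcriptome. Knowing which gRNA a cell received does not tell you whether
the knock-down actually perturbed that cell: guide efficiency varies from
cell to cell, and the downstream transcriptomic consequence of a successful
knock-down has incomplete penetrance. Bulk-style differential expression
between "targeted" and "control" cells therefore dilutes real signatures
with unperturbed cells. `ssaescreen` addresses both problems jointly: it
selects the genes that discriminate targeted from control cells
(structured sparsity) and the cells in which the perturbation is actually
present (perturbation scores), and reports a ranked, direction-annotated,
stability-flagged perturbation signature.

## Model

For one target gene in one experimental condition, let `X` (n cells by d
genes) be the concatenated raw UMI counts of negative-control cells and
gRNA-targeted cells, and `Y` the binary labels (0 = control, 1 =
targeted). The model is a symmetric fully connected autoencoder:

* encoder: `d -> h` linear, ReLU, `h -> k` linear with latent dimension
  `k = 2` (one coordinate per class);
* decoder, mirroring the encoder: `2 -> h` linear, ReLU, `h -> d` linear
  producing the reconstruction `X_hat`;
* a softmax over the two latent coordinates gives each cell a class
  probability; the class-1 probability is the cell's *perturbation score*.

Training minimizes the joint objective

```
Loss(W) = CE(softmax(Z), Y) + lambda * Huber(X_hat - X)   s.t.  ||W1||_{1,1} <= eta
```

a cross-entropy classification term plus a Huber (smooth-l1)
reconstruction term, subject to an l1,1-ball constraint on the first
encoder layer `W1`. The Huber loss is preferred to squared error because
raw UMI counts contain occasional huge values. The reconstruction term
regularizes the latent space — the latent code must retain enough of the
transcriptome to rebuild it, which discourages degenerate solutions that
classify on noise.

### Structured sparsity and gene selection

The constraint set is the l1,1 ball: the sum over genes of the l1 norms of
their fan-out weight rows must not exceed `eta`. After every Adam step the
first layer is projected back onto this ball with a *bilevel* projection:

1. the vector of per-gene row norms is projected onto the l1 ball of
   radius `eta` (exact, sort-based), allocating a budget per gene;
2. each row is projected onto the l1 ball of its budget.

Genes whose budget is zero have their entire row zeroed: the gene is
disconnected from the network. This is what makes the operator a feature
*selector* rather than a mere shrinker. Note the bilevel operator is not
the exact Euclidean projection onto the l1,1 ball — the exact projection
is entrywise soft-thresholding of the flattened matrix (the l1,1 norm of
a matrix is the l1 norm of its vectorization) and rarely zeroes whole
rows. The two generally differ: the row stage soft-thresholds row *norms*
by a level `lambda1` and each surviving row is then thresholded at its
own level, whereas the exact projection applies one common entrywise
threshold; they coincide only when those per-row levels all equal the
global one (for instance when every surviving row has a single nonzero,
as in `rbind(c(2,0), c(0,2))` with `eta = 2`). The test suite compares
the operator against an exact-projection oracle, verifies that it is
feasible, idempotent, and never closer to the input than the true
projection, and records the divergence. The bilevel form is used
deliberately: it trades Euclidean optimality for row-level selection
semantics.

### Double-descent training

Training follows a lottery-ticket-style two-phase schedule: train the full
network under projection (phase 1); record which genes survived; rewind
the surviving rows of the first layer to their initial values and freeze
the deselected rows at exactly zero; retrain the masked network under the
same projection (phase 2). Projection is applied after every optimizer
step, so iterates are always feasible; the support can only shrink in
phase 2, never grow.

### Two-round cell selection

Round 1 trains on all control and targeted cells with stratified k-fold
cross-validation; every cell receives an out-of-fold perturbation score
(predicted by models that never saw it), averaged over initialization
seeds. Targeted cells with score strictly above 0.5 are "perturbed", the
rest "non-perturbed"; a score of exactly 0.5 is conservatively assigned
non-perturbed (the two strict inequalities of the decision rule leave the
boundary undefined). Out-of-fold rather than refit-on-everything scoring
avoids selecting cells with an overfit classifier.

Round 2 re-fits on the perturbed cells against an equal number of control
cells sampled without replacement — a fresh subsample per seed — and the
signature is built from these balanced models. When fewer perturbed cells
than `min_cells_per_class` (default 40) pass the threshold, round 2 is
skipped and only round-1 results are reported: with fewer than ~10
positives per fold a stratified 4-fold cross-validation is no longer
meaningful. This mirrors low-penetrance screens in which no cell
selection is possible.

Unweighted cross-entropy in round 1 is a deliberate default. The class
masses then set the prior odds of the ambiguous region: when controls are
in the majority, a targeted cell with no detectable perturbation scores
below 0.5 and is correctly left unselected. Inverse-frequency weighting
(available via `class_weighting = TRUE`, useful when targeted cells
heavily outnumber controls) pins that ambiguous score to almost exactly
0.5, where sampling noise arbitrarily flags about half the undetectable
cells — it would make the score non-selective precisely in the screens
where selectivity matters.

### Signature, attribution, stability

Per-gene importance of a trained model is computed by sampled-baseline
path integration (expected gradients, a Shapley-value approximation): the
gradient of the class-1 logit is integrated along straight paths from
control baselines to each perturbed cell and multiplied by the input
difference; the per-gene score is the mean absolute attribution. The
attribution target is the pre-softmax logit (standard practice; avoids
softmax saturation). Deselected genes receive exactly zero. Within each
round-2 model, selected genes are ranked 1..s by attribution; genes
outside the model's support take the worst rank d (a gene absent from a
run's support is maximally non-discriminant for that run). Ranks are
aggregated across seeds into a mean and standard deviation; genes are
reported sorted by mean rank, annotated with the log2 fold change between
perturbed and control cells (library-size normalized, pseudocount 1), and
flagged `stable` when two conditions hold: the rank standard deviation is
at most `sd_threshold` (default 3 — the gene occupies essentially the
same rank in every repetition; an absolute cut-off, because on a
pure-noise screen the best-mean-ranked genes still show rank spreads of
tens of positions, so any panel-size-relative cut-off lenient enough to
call those stable is meaningless) and the gene is materially regulated,
`|log2fc| >= min_abs_lfc` (default 0.5). The second condition exists
because with only a few repetitions rank spread alone cannot separate a
real signature gene from the occasional noise gene that holds its rank —
but the two differ sharply in effect size, near zero for noise. An
unstable top rank is itself informative: it is the signature of a screen
where only the target gene responds.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eta` | 25 | l1,1 radius; smaller = fewer genes kept. 25 keeps roughly 10% of a 1000-gene panel. Tune per dataset with `tune_eta()` (golden-section search on cross-validated accuracy, which is concave in eta in practice). |
| `lambda` | 1 | weight of the Huber reconstruction term (dimensionless). |
| `hidden_dim` | 100 | hidden width h. |
| `lr`, `batch_size` | 1e-3, 128 | Adam step size and minibatch size. |
| `epochs_phase1/2` | 15 / 15 | epoch budget of each descent; deliberately short (see below). |
| `n_folds`, `n_seeds` | 4, 3 | cross-validation folds; initialization seeds averaged over. |
| `huber_delta` | 1 | quadratic-to-linear transition of the Huber loss, in count units. |
| `min_cells_per_class` | 40 | minimum perturbed cells to attempt round 2 (>= 10 positives per fold). |

Defaults are sized for desk-scale screens (hundreds of cells, ~10^3
genes). The optimizer, architecture and fold/seed counts follow the
method's published configuration; the epoch budget, learning rate and
batch size are this package's choices, exposed in `train_config()`.

The short epoch budget is a deliberate regularizer, not a shortcut. A
targeted cell in which the knock-down produced no transcriptomic effect
is statistically identical to a control cell, yet carries label 1; given
enough epochs the network memorizes noise-gene patterns to "explain"
such cells, which degrades control specificity and floods the perturbed
set with false positives. Early stopping keeps the score selective.

## The synthetic-data generator

`simulate_cropseq()` generates the ground-truth datasets every downstream
stage is tested against. It emulates:

* log-normal baseline gene means (meanlog 0, sdlog 1.2 — a typical
  single-cell expression profile where most genes sit below ~1 UMI/cell);
* negative-binomial UMI counts, `Var = mu + mu^2/theta` (dispersion
  `theta = 2` by default, i.e. strongly overdispersed);
* a target gene knocked down in **every** targeted cell (the gRNA is
  present in all of them) with per-cell efficiency drawn from a truncated
  normal centered at `knockdown_factor` — knock-down strength varies
  between cells;
* a planted log2-fold-change signature expressed **only** in a Bernoulli
  `frac_perturbed` subset of targeted cells (the penetrance of the
  perturbation);
* untouched negative-control cells.

Two expression-level choices are deliberate. The target gene defaults to
a *low* mean (0.5 UMI/cell), typical of lncRNA CRISPRi targets: its
knock-down is then a weak signal in any single cell but a consistent one
across the whole targeted population — which is why the target gene ranks
at the top of discriminant-feature lists even in screens with no stable
downstream signature, while cells are *not* classified perturbed on the
target gene alone. Signature genes are drawn among genes with baseline
mean at least 3 UMI/cell: observable perturbation signatures consist of
reasonably abundant transcripts (glycolytic enzymes, secreted factors),
not of genes at the detection limit. An abundantly expressed target
(e.g. mean 10) makes every targeted cell individually recognizable from
that one gene, so cell selection saturates at 100% regardless of
penetrance — a regime the generator can produce (set `target_log_mean`)
but that does not reproduce the low-penetrance phenomenology of real
screens.

What the generator does **not** emulate: hashing/multiplexing artifacts,
doublets, ambient RNA, batch effects, gene-gene correlation beyond the
planted signature, and library-size variation beyond what NB sampling
produces. Passing tests on this generator therefore demonstrates that the
method recovers planted, independent, NB-distributed signals at realistic
noise levels — not that it is robust to every artifact of real droplet
data.

## Numerical choices

* l1-ball projection: exact sort-based algorithm (O(m log m)), not an
  iterative approximation; deterministic and testable against an
  independent bisection oracle.
* Softmax is computed with row-max subtraction; cross-entropy clips
  probabilities at 1e-12.
* A score of exactly 0.5 is non-perturbed (see above). Ties in mean rank
  are broken by higher mean attribution, then gene id.
* All randomness (initialization, fold assignment, batch shuffling,
  control subsampling, attribution baselines) is derived from one run
  seed through tagged sub-seed hashing: adding one stochastic step never
  perturbs the streams of the others, and every result is bit-reproducible
  from the seed.
* The training loop has two interchangeable engines: a plain-R reference
  implementation and a compiled (RcppArmadillo) production path; the test
  suite asserts their step-for-step numerical equivalence, and the
  analytic gradients are checked against central finite differences.
* Degenerate inputs: single-class training data, classes smaller than the
  fold count, empty baseline pools and empty perturbed sets are rejected
  with explicit errors; a control pool smaller than the perturbed set
  triggers a documented all-controls fallback with a warning.

## Problem sizes used in the tests

Unit tests run on small screens (40-60 genes, ~100 cells, reduced epoch
budgets). The end-to-end validation battery uses the generator's default
study conditions: 1000 genes, 300 control + 300 targeted cells, 10
signature genes at |log2FC| = 1.5, 70% penetrance, 90% knock-down,
NB dispersion 2, 4-fold cross-validation over 3 seeds — and a
low-penetrance variant (5%, 200 targeted cells) for the skip behavior,
plus matched null simulations. These sizes keep a full planted-recovery
run in the minutes range on one core while leaving the per-gene and
per-cell signal-to-noise in a realistic regime.

## What penetrance does to round-1 accuracy

One structural fact is worth spelling out because it shapes every
round-1 number. If a fraction `f` of targeted cells is actually
perturbed and the unperturbed remainder is statistically
indistinguishable from controls, then any classifier's expected round-1
accuracy is capped near `(n_ctrl + f * n_targ) / (n_ctrl + n_targ)` —
with 300 + 300 cells and 70% penetrance, 0.85. Exceeding that cap
requires the unperturbed targeted cells to be individually detectable
(e.g. through an abundantly expressed target gene), and a generator in
that regime flags essentially all targeted cells as perturbed at any
penetrance, destroying the selectivity that the low-penetrance skip
behavior depends on. Round-1 accuracy under incomplete penetrance is
therefore a biased, capped measure of model quality; the round-2
accuracy on selected cells is the informative one. This is precisely
the motivation for cell selection.

## Known limitations

* The bilevel operator is not the exact l1,1 projection (see above); this
  is a property of the published operator, documented rather than hidden.
* Attribution is a sampled approximation of Shapley values; only its
  fixed-ReLU-region behavior is exact (and tested). Rankings, not raw
  attribution magnitudes, are the reported quantity.
* With `k = 2` the method is binary by construction; multi-class screens
  need one run per target, as the per-(target, condition) sweep does.
* Raw counts enter the model undepth-normalized by default (faithful to
  the method's definition); an optional library-size + log1p
  normalization flag exists in `assemble_dataset()` for robustness
  experiments.
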