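## Reading 10x-style count matrices and cell annotations, assembling the
## per-(target, condition) labeled datasets the classifier consumes, and
## writing result tables.

CONTROL_SENTINEL <- "none"

#' Construct a cells x genes count matrix container
#'
#' @param values Nonnegative integer matrix, cells in rows, genes in columns.
#' @param gene_ids Character vector of unique gene identifiers (columns).
#' @param barcodes Character vector of unique cell barcodes (rows).
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(values, gene_ids, barcodes) {
  values <- as.matrix(values)
  if (anyNA(values)) stopf("count_matrix: missing values not allowed")
  if (any(values < 0)) stopf("count_matrix: negative counts not allowed")
  if (any(values != round(values))) {
    stopf("count_matrix: counts must be integers")
  }
  if (length(gene_ids) != ncol(values)) {
    stopf("count_matrix: %d gene ids for %d matrix columns",
          length(gene_ids), ncol(values))
  }
  if (length(barcodes) != nrow(values)) {
    stopf("count_matrix: %d barcodes for %d matrix rows",
          length(barcodes), nrow(values))
  }
  if (anyDuplicated(gene_ids)) stopf("count_matrix: duplicate gene ids")
  if (anyDuplicated(barcodes)) stopf("count_matrix: duplicate barcodes")
  storage.mode(values) <- "double"
  dimnames(values) <- list(barcodes, gene_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 barcodes = as.character(barcodes)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d cells x %d genes, %.0f total UMIs\n",
              length(x$barcodes), length(x$gene_ids), sum(x$values)))
  invisible(x)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, a gene/feature TSV (`features.tsv` or `genes.tsv`)
#' and `barcodes.tsv` in `directory`. On-disk orientation (genes x cells,
#' the 10x convention, or cells x genes) is detected from the TSV lengths;
#' the returned matrix is always cells x genes.
#'
#' @param directory Path containing the triplet files.
#' @return A [count_matrix()].
#' @export
read_counts_mtx <- function(directory) {
  if (!dir.exists(directory)) stopf("read_counts_mtx: no directory '%s'", directory)
  mtx <- file.path(directory, "matrix.mtx")
  if (!file.exists(mtx)) stopf("read_counts_mtx: missing %s", mtx)
  feat <- Filter(file.exists,
                 file.path(directory, c("features.tsv", "genes.tsv")))
  if (length(feat) == 0) {
    stopf("read_counts_mtx: missing features.tsv/genes.tsv in %s", directory)
  }
  bc <- file.path(directory, "barcodes.tsv")
  if (!file.exists(bc)) stopf("read_counts_mtx: missing %s", bc)

  M <- as.matrix(Matrix::readMM(mtx))
  genes <- utils::read.delim(feat[[1L]], header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  barcodes <- utils::read.delim(bc, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]

  dims_ok <- function(nr, nc) nr == length(barcodes) && nc == length(genes)
  if (dims_ok(nrow(M), ncol(M))) {
    # stored cells x genes
  } else if (dims_ok(ncol(M), nrow(M))) {
    M <- t(M)
  } else {
    stopf(paste0("read_counts_mtx: matrix is %d x %d but there are ",
                 "%d genes and %d barcodes"),
          nrow(M), ncol(M), length(genes), length(barcodes))
  }
  if (any(M < 0) || any(M != round(M))) {
    stopf("read_counts_mtx: counts must be nonnegative integers")
  }
  count_matrix(M, genes, barcodes)
}

#' Write a count matrix as a 10x-style MatrixMarket triplet
#'
#' Stores the matrix genes x cells on disk (the 10x convention), plus
#' `features.tsv` and `barcodes.tsv`.
#'
#' @param counts A [count_matrix()].
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_counts_mtx <- function(counts, directory) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  M <- Matrix::Matrix(t(counts$values), sparse = TRUE)
  Matrix::writeMM(M, file.path(directory, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(directory, "features.tsv"))
  writeLines(counts$barcodes, file.path(directory, "barcodes.tsv"))
  invisible(directory)
}

#' Read a dense cells x genes count table (CSV/TSV)
#'
#' First column must hold cell barcodes; remaining column names are gene
#' identifiers.
#'
#' @param path Delimited text file; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab).
#' @return A [count_matrix()].
#' @export
read_counts_dense <- function(path) {
  if (!file.exists(path)) stopf("read_counts_dense: no file '%s'", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(df[, -1L, drop = FALSE]),
               colnames(df)[-1L], df[[1L]])
}

#' Read the per-cell annotation table
#'
#' A delimited table with columns `barcode`, `grna_id`, `target_gene`,
#' `condition`. Cells whose `target_gene` is the sentinel `"none"` are
#' negative controls; `is_control` is derived, never read.
#'
#' @param path TSV/CSV file path.
#' @return A data.frame with one row per cell and the derived `is_control`
#'   logical column.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("read_annotations: no file '%s'", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("barcode", "grna_id", "target_gene", "condition")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("read_annotations: missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  dup <- df$barcode[duplicated(df$barcode)]
  if (length(dup)) {
    stopf("read_annotations: duplicate barcode(s): %s",
          paste(unique(dup), collapse = ", "))
  }
  df$is_control <- df$target_gene == CONTROL_SENTINEL
  df[, c(required, "is_control")]
}

#' Assemble the labeled dataset for one (target gene, condition) pair
#'
#' Concatenates the negative-control cells (label 0) and the cells targeted
#' for `target_gene` (label 1) observed under `condition`, in that order.
#' By default X holds the raw UMI counts; per-cell library-size
#' normalization with log1p can be switched on for robustness experiments.
#'
#' @param counts A [count_matrix()] covering all cells.
#' @param annotations Annotation data.frame from [read_annotations()].
#' @param target_gene Target gene whose gRNA-carrying cells form class 1.
#' @param condition Experimental condition to restrict to.
#' @param normalize If `TRUE`, X becomes `log1p(count / libsize * mean libsize)`.
#'   Default `FALSE` (raw counts).
#' @param min_cells_expressing Drop genes detected in fewer cells than this
#'   (default 0: keep every gene).
#' @return A `labeled_dataset`: list with `X` (n x d), `Y` (0/1), `gene_ids`,
#'   `barcodes`, `target_gene`, `condition`.
#' @export
assemble_dataset <- function(counts, annotations, target_gene, condition,
                             normalize = FALSE, min_cells_expressing = 0L) {
  stopifnot(inherits(counts, "count_matrix"))
  ann <- annotations[annotations$condition == condition, , drop = FALSE]
  ann <- ann[ann$barcode %in% counts$barcodes, , drop = FALSE]
  ctrl_bc <- ann$barcode[ann$is_control]
  targ_bc <- ann$barcode[!ann$is_control & ann$target_gene == target_gene]
  if (length(ctrl_bc) == 0) {
    stopf("assemble_dataset: no control cells in condition '%s'", condition)
  }
  if (length(targ_bc) == 0) {
    stopf("assemble_dataset: no cells targeted for '%s' in condition '%s'",
          target_gene, condition)
  }
  bc <- c(ctrl_bc, targ_bc)
  X <- counts$values[match(bc, counts$barcodes), , drop = FALSE]
  Y <- c(rep(0L, length(ctrl_bc)), rep(1L, length(targ_bc)))
  gene_ids <- counts$gene_ids
  if (min_cells_expressing > 0) {
    keep <- colSums(X > 0) >= min_cells_expressing
    X <- X[, keep, drop = FALSE]
    gene_ids <- gene_ids[keep]
  }
  if (normalize) {
    lib <- rowSums(X)
    lib[lib == 0] <- 1
    X <- log1p(X / lib * mean(lib))
  }
  structure(list(X = X, Y = Y, gene_ids = gene_ids, barcodes = bc,
                 target_gene = target_gene, condition = condition),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "<labeled_dataset> %s / %s: %d controls + %d targeted cells, %d genes\n",
    x$target_gene, x$condition, sum(x$Y == 0), sum(x$Y == 1),
    length(x$gene_ids)))
  invisible(x)
}

#' Write a perturbation signature table to TSV
#'
#' Columns: gene, attribution, mean_rank, sd_rank, log2fc, direction,
#' stable; rows sorted by mean rank.
#'
#' @param signature A `signature_table` (see [build_signature()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(signature, path) {
  df <- as.data.frame(signature)
  if (nrow(df) == 0) stopf("write_signature_table: empty signature")
  df <- df[order(df$mean_rank), , drop = FALSE]
  cols <- c("gene", "attribution", "mean_rank", "sd_rank", "log2fc",
            "direction", "stable")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
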