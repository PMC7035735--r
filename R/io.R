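#' Construct a validated count matrix
#'
#' The package's basic container: an `M x N` matrix of non-negative integer
#' transcript counts with cells as rows and genes as columns, plus unique
#' cell and gene identifiers.
#'
#' @param values `M x N` matrix of non-negative integers.
#' @param cell_ids Character vector of M unique cell identifiers.
#' @param gene_ids Character vector of N unique gene identifiers.
#' @return An object of class `count_matrix` with fields `values`,
#'   `cell_ids`, `gene_ids`.
#' @export
count_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  bad <- which(!is.finite(values) | values < 0 | values != floor(values))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf(
      "invalid count at cell %d, gene %d: %s (counts must be non-negative integers)",
      i, j, format(values[bad[1]])), call. = FALSE)
  }
  if (length(cell_ids) != nrow(values) || anyDuplicated(cell_ids)) {
    stop("'cell_ids' must be unique and match the number of rows", call. = FALSE)
  }
  if (length(gene_ids) != ncol(values) || anyDuplicated(gene_ids)) {
    stop("'gene_ids' must be unique and match the number of columns", call. = FALSE)
  }
  dimnames(values) <- NULL
  structure(list(values = values, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %.1f%% zeros\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$values == 0)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a count matrix from disk
#'
#' Two on-disk forms are supported, both with cells as rows:
#' * `mtx` — MatrixMarket coordinate file (1-based indices per the
#'   standard), with companion one-id-per-line text files for cell (row)
#'   and gene (column) names, derived from the `.mtx` path by replacing the
#'   extension with `.barcodes.txt` and `.genes.txt`.
#' * `csv` / `tsv` — dense table with a header row of gene ids and a first
#'   column of cell ids.
#'
#' @param path Path to the `.mtx` or dense table file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension when missing.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("cannot guess format from extension; pass 'format'",
                          call. = FALSE))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    base <- sub("\\.mtx$", "", path)
    cf <- paste0(base, ".barcodes.txt")
    gf <- paste0(base, ".genes.txt")
    for (f in c(cf, gf)) {
      if (!file.exists(f)) stop(sprintf("companion file not found: %s", f), call. = FALSE)
    }
    count_matrix(m, readLines(cf), readLines(gf))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                            row.names = 1, stringsAsFactors = FALSE)
    count_matrix(as.matrix(df), rownames(df), colnames(df))
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: writes either the MatrixMarket triplet
#' (`.mtx` plus `.barcodes.txt` / `.genes.txt`) or a dense CSV/TSV.
#'
#' @param counts A [count_matrix()].
#' @param path Output path (extension determines companions for `mtx`).
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(counts$values, sparse = TRUE), path)
    base <- sub("\\.mtx$", "", path)
    writeLines(counts$cell_ids, paste0(base, ".barcodes.txt"))
    writeLines(counts$gene_ids, paste0(base, ".genes.txt"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- as.data.frame(counts$values)
    colnames(df) <- counts$gene_ids
    rownames(df) <- counts$cell_ids
    utils::write.table(df, path, sep = sep, quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Read / write a cell-label vector
#'
#' Labels are stored as a single-column text file, one label per cell, in
#' cell order, no header.
#'
#' @param path File path.
#' @return Character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  readLines(path)
}

#' @rdname read_labels
#' @param labels Character vector to write.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.character(labels), path)
  invisible(path)
}

#' Select the highest-variance genes
#'
#' Restricts a count matrix to the `n_genes` genes of largest across-cell
#' variance of the raw counts (population variance, i.e. divided by M),
#' ordered by descending variance. Ties are broken by the lower original
#' gene index, making the selection deterministic. 720 genes is the
#' standard panel size used throughout.
#'
#' @param counts A [count_matrix()].
#' @param n_genes Number of genes to keep (default 720).
#' @return A [count_matrix()] of the selected genes, with the indices of
#'   the selected genes in the source matrix attached as
#'   `$selected_gene_indices`.
#' @export
select_top_variance_genes <- function(counts, n_genes = 720) {
  stopifnot(inherits(counts, "count_matrix"))
  N <- ncol(counts$values)
  if (n_genes <= 0) stop("'n_genes' must be positive", call. = FALSE)
  if (n_genes > N) {
    stop(sprintf("'n_genes' (%d) exceeds the number of genes (%d)", n_genes, N),
         call. = FALSE)
  }
  M <- nrow(counts$values)
  v <- colMeans(counts$values^2) - colMeans(counts$values)^2 # population variance
  ord <- order(-v, seq_len(N)) # descending variance, lower index wins ties
  keep <- ord[seq_len(n_genes)]
  out <- count_matrix(counts$values[, keep, drop = FALSE],
                      counts$cell_ids, counts$gene_ids[keep])
  out$selected_gene_indices <- keep
  out
}

#' Log-transform a count matrix
#'
#' Applies the standard `log2(1 + C)` transform entrywise, producing the
#' matrix the encoder consumes. Gene-selection metadata is carried through.
#'
#' @param counts A [count_matrix()] (typically after
#'   [select_top_variance_genes()]).
#' @return An object of class `processed_matrix` with fields `values`
#'   (`M x G` non-negative reals), `cell_ids`, `source_gene_ids`, and
#'   `selected_gene_indices`.
#' @export
log_transform <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  idx <- counts$selected_gene_indices
  if (is.null(idx)) idx <- seq_len(ncol(counts$values))
  structure(list(values = log2(1 + counts$values),
                 cell_ids = counts$cell_ids,
                 source_gene_ids = counts$gene_ids,
                 selected_gene_indices = idx),
            class = "processed_matrix")
}

#' @export
dim.processed_matrix <- function(x) dim(x$values)

#' Subset cells of a count or processed matrix
#'
#' Row-subsets the matrix and its cell identifiers, e.g. by the `train` or
#' `test` component of [split_train_test()].
#'
#' @param x A [count_matrix()] or a `processed_matrix`.
#' @param idx Integer vector of cell indices (1-based).
#' @return An object of the same class restricted to the selected cells.
#' @export
subset_cells <- function(x, idx) {
  if (inherits(x, "count_matrix")) {
    out <- count_matrix(x$values[idx, , drop = FALSE], x$cell_ids[idx],
                        x$gene_ids)
    out$selected_gene_indices <- x$selected_gene_indices
    out
  } else if (inherits(x, "processed_matrix")) {
    x$values <- x$values[idx, , drop = FALSE]
    x$cell_ids <- x$cell_ids[idx]
    x
  } else {
    stop("'x' must be a count_matrix or processed_matrix", call. = FALSE)
  }
}

#' Reproducible train/test split
#'
#' Uniformly random partition of cells into a training and a testing set.
#' The training-set size is `round(train_fraction * n_cells)` with
#' round-half-up. The canonical protocol is an 80/20 split.
#'
#' @param n_cells Number of cells (at least 2).
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Integer seed; the split is a pure function of
#'   `(n_cells, train_fraction, seed)`.
#' @return An object of class `split_indices` with sorted integer fields
#'   `train`, `test` (1-based, disjoint, covering `1..n_cells`) and `seed`.
#' @export
split_train_test <- function(n_cells, train_fraction = 0.8, seed = 0) {
  if (n_cells < 2) stop("'n_cells' must be at least 2", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- floor(train_fraction * n_cells + 0.5) # round-half-up
  perm <- .with_local_seed(seed, sample.int(n_cells))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 test = sort(perm[-seq_len(n_train)]),
                 seed = seed),
            class = "split_indices")
}
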