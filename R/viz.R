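#' Two-step 2-D embedding: latent projection then t-SNE
#'
#' The visualization recipe for higher-dimensional models: project cells
#' with a trained K = 10 model, then run t-SNE (perplexity 30) on the
#' latent coordinates to obtain 2-D positions. Seed-reproducible.
#'
#' @param model A trained [train_model()] result with `latent_dim == 10`
#'   (pass `allow_any_K = TRUE` to override).
#' @param x A `processed_matrix` or matrix over the training gene panel.
#' @param labels Optional label vector carried into the result.
#' @param perplexity t-SNE perplexity (default 30; reduced automatically
#'   for tiny inputs).
#' @param seed Integer seed.
#' @param allow_any_K Permit latent dimensions other than 10.
#' @return An object of class `embedding_2d`: list with `coordinates`
#'   (`M x 2`), `labels`, `method_tag`.
#' @export
two_step_embed <- function(model, x, labels = NULL, perplexity = 30, seed = 0,
                           allow_any_K = FALSE) {
  stopifnot(inherits(model, "avae_model"))
  if (model$config$latent_dim != 10 && !allow_any_K) {
    stop("the two-step recipe expects a K = 10 model ",
         "(set allow_any_K = TRUE to override)", call. = FALSE)
  }
  if (!requireNamespace("Rtsne", quietly = TRUE)) {
    stop("the 'Rtsne' package is required for two_step_embed", call. = FALSE)
  }
  z <- project(model, x)
  perp <- min(perplexity, (nrow(z) - 1) %/% 3)
  y <- .with_local_seed(seed, Rtsne::Rtsne(z, dims = 2, perplexity = perp,
                                           check_duplicates = FALSE, pca = FALSE)$Y)
  embedding_2d(y, labels = labels,
               method_tag = sprintf("AVAE-DM (K=%d) + t-SNE", model$config$latent_dim))
}

#' Construct a 2-D embedding object
#'
#' @param coordinates `M x 2` numeric matrix.
#' @param labels Optional label vector of length M.
#' @param method_tag Short description of the producing method.
#' @return An object of class `embedding_2d`.
#' @export
embedding_2d <- function(coordinates, labels = NULL, method_tag = "embedding") {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 2) {
    stop("'coordinates' must have exactly two columns", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != nrow(coordinates)) {
    stop("'labels' length must match the number of rows", call. = FALSE)
  }
  structure(list(coordinates = coordinates, labels = labels,
                 method_tag = method_tag), class = "embedding_2d")
}

#' Keep only the most abundant cell types
#'
#' Retains cells whose label is among the `n_types` most frequent labels
#' (ties broken lexicographically), the standard trick for readable 2-D
#' plots of datasets with many cell types.
#'
#' @param x Matrix, `processed_matrix`, or `count_matrix` with cells as rows.
#' @param labels Label vector, one per cell.
#' @param n_types Number of label classes to keep (default 10).
#' @return List with `x` (subset, same type as the input) and `labels`.
#' @export
filter_top_cell_types <- function(x, labels, n_types = 10) {
  if (n_types < 1) stop("'n_types' must be at least 1", call. = FALSE)
  counts <- table(labels)
  ord <- order(-as.numeric(counts), names(counts)) # frequency desc, then lexicographic
  keep_labels <- names(counts)[ord][seq_len(min(n_types, length(counts)))]
  keep <- as.character(labels) %in% keep_labels
  sub <- if (inherits(x, "count_matrix")) {
    count_matrix(x$values[keep, , drop = FALSE], x$cell_ids[keep], x$gene_ids)
  } else if (inherits(x, "processed_matrix")) {
    out <- x
    out$values <- x$values[keep, , drop = FALSE]
    out$cell_ids <- x$cell_ids[keep]
    out
  } else {
    as.matrix(x)[keep, , drop = FALSE]
  }
  list(x = sub, labels = labels[keep])
}

#' Scatter plot of a 2-D embedding colored by label
#'
#' One point per cell, a categorical palette with classes ordered by
#' frequency (stable across figures), a label legend, and the method tag as
#' title. Written as PNG (and optionally SVG).
#'
#' @param embedding An [embedding_2d()].
#' @param path Output file path ending in `.png` or `.svg`.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
scatter_plot <- function(embedding, path, width = 7, height = 6) {
  stopifnot(inherits(embedding, "embedding_2d"))
  if (nrow(embedding$coordinates) == 0) {
    stop("cannot plot an empty embedding", call. = FALSE)
  }
  labels <- embedding$labels
  if (is.null(labels)) labels <- rep("cell", nrow(embedding$coordinates))
  freq <- sort(table(labels), decreasing = TRUE)
  classes <- names(freq)
  pal <- grDevices::hcl.colors(max(3, length(classes)), "Dark 3")[seq_along(classes)]
  col <- pal[match(as.character(labels), classes)]
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    png = function() grDevices::png(path, width = width, height = height,
                                    units = "in", res = 150),
    svg = function() grDevices::svg(path, width = width, height = height),
    stop("'path' must end in .png or .svg", call. = FALSE))
  dev()
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 3, 1))
  graphics::plot(embedding$coordinates, col = col, pch = 16, cex = 0.6,
                 xlab = "dim 1", ylab = "dim 2", main = embedding$method_tag)
  graphics::legend("topright", legend = classes, col = pal, pch = 16,
                   cex = 0.7, bty = "n")
  invisible(path)
}

#' Export a 2-D embedding as CSV
#'
#' Columns: `cell_id`, `x`, `y`, `label`.
#'
#' @param embedding An [embedding_2d()].
#' @param path Output CSV path.
#' @param cell_ids Optional cell identifiers (defaults to `cell_<i>`).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, cell_ids = NULL) {
  stopifnot(inherits(embedding, "embedding_2d"))
  n <- nrow(embedding$coordinates)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  labs <- embedding$labels
  if (is.null(labs)) labs <- NA
  utils::write.csv(data.frame(cell_id = cell_ids,
                              x = embedding$coordinates[, 1],
                              y = embedding$coordinates[, 2],
                              label = labs),
                   path, row.names = FALSE)
  invisible(path)
}
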