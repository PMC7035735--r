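#' K-means clustering of a latent embedding
#'
#' K-means with k-means++ seeding and 10 restarts, keeping the solution of
#' lowest within-cluster sum of squares. The k-means++ seeding step (first
#' center uniform, subsequent centers sampled proportionally to squared
#' distance from the nearest chosen center) is written here; Lloyd
#' iterations are delegated to [stats::kmeans()]. Deterministic given
#' `seed`.
#'
#' @param embedding `M x K` numeric matrix.
#' @param k Number of clusters (at most M).
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @return An object of class `clustering_result` with fields
#'   `assignments` (integer vector), `k`, `inertia`, `seed`.
#' @export
kmeans_cluster <- function(embedding, k, seed = 0, restarts = 10) {
  embedding <- as.matrix(embedding)
  M <- nrow(embedding)
  if (k > M) stop(sprintf("'k' (%d) exceeds the number of points (%d)", k, M),
                  call. = FALSE)
  if (k < 1) stop("'k' must be positive", call. = FALSE)
  if (k == M) {
    # one point per cluster; stats::kmeans() rejects this boundary case
    return(structure(list(assignments = seq_len(M), k = as.integer(k),
                          inertia = 0, seed = seed),
                     class = "clustering_result"))
  }
  .with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- .kmeanspp_centers(embedding, k)
      fit <- suppressWarnings(
        stats::kmeans(embedding, centers = centers, iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(assignments = as.integer(best$cluster), k = as.integer(k),
                   inertia = best$tot.withinss, seed = seed),
              class = "clustering_result")
  })
}

.kmeanspp_centers <- function(x, k) {
  M <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(M, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / M, M)
      idx[j] <- sample.int(M, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
    }
  }
  # jitter-free duplicate guard: kmeans() requires distinct centers
  ctr <- x[idx, , drop = FALSE]
  if (anyDuplicated(ctr)) {
    ctr <- ctr + matrix(stats::rnorm(length(ctr), sd = 1e-9), nrow(ctr))
  }
  ctr
}

#' Normalized mutual information between two labelings
#'
#' `NMI = MI(X; Y) / sqrt(H(X) H(Y))`, computed from the joint contingency
#' table in natural log (the base cancels in the ratio). When either
#' labeling has zero entropy (a single class) the score is defined as 0 and
#' a warning is emitted.
#'
#' @param predicted,truth Label vectors of equal length (any atomic type).
#' @return A number in `[0, 1]`.
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
#' @export
nmi <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("'predicted' and 'truth' must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0) stop("labels must be nonempty", call. = FALSE)
  tab <- table(predicted, truth)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) {
    warning("degenerate labeling (single class); NMI defined as 0")
    return(0)
  }
  outer_p <- outer(px, py)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer_p[nz]))
  max(0, min(1, mi / sqrt(hx * hy)))
}

#' Cluster an embedding and score it against ground truth
#'
#' The standard evaluation protocol: K-means with k set to the number of
#' distinct ground-truth classes, scored by NMI against those labels.
#'
#' @param embedding `M x K` numeric matrix.
#' @param truth Ground-truth label vector (at least two classes).
#' @param seed Integer seed for the clustering.
#' @return NMI score in `[0, 1]`.
#' @export
evaluate_embedding <- function(embedding, truth, seed = 0) {
  k <- length(unique(truth))
  if (k < 2) {
    stop("ground truth must contain at least two classes", call. = FALSE)
  }
  cl <- kmeans_cluster(embedding, k, seed = seed)
  nmi(cl$assignments, truth)
}

#' Benchmark baseline embeddings
#'
#' Embeds the processed expression matrix with standard methods (PCA via
#' [stats::prcomp()]; t-SNE via \pkg{Rtsne} at perplexity 30; UMAP via
#' \pkg{uwot}) to `K` dimensions and scores each with
#' [evaluate_embedding()]. t-SNE is restricted to `K <= 3` and reported as
#' `"N/A"` above that; methods whose package is unavailable are likewise
#' recorded as `"N/A"`, never an error.
#'
#' @param x A `processed_matrix` or plain numeric matrix.
#' @param methods Subset of `c("pca", "tsne", "umap")`.
#' @param K Embedding dimension.
#' @param truth Ground-truth labels.
#' @param seed Integer seed.
#' @return Data frame with columns `method`, `K`, `seed`, `nmi` (`nmi` is
#'   `NA` for not-applicable entries, printed as "N/A").
#' @export
run_baselines <- function(x, methods = c("pca", "tsne", "umap"), K, truth,
                          seed = 0) {
  methods <- match.arg(methods, several.ok = TRUE)
  xm <- if (inherits(x, "processed_matrix")) x$values else as.matrix(x)
  rows <- lapply(methods, function(m) {
    emb <- switch(m,
      pca = {
        K_eff <- min(K, ncol(xm), nrow(xm))
        stats::prcomp(xm, center = TRUE, scale. = FALSE)$x[, seq_len(K_eff), drop = FALSE]
      },
      tsne = {
        if (K > 3 || !requireNamespace("Rtsne", quietly = TRUE)) NULL
        else .with_local_seed(seed, Rtsne::Rtsne(
          xm, dims = K, perplexity = min(30, (nrow(xm) - 1) %/% 3),
          check_duplicates = FALSE, pca = TRUE)$Y)
      },
      umap = {
        if (!requireNamespace("uwot", quietly = TRUE)) NULL
        else .with_local_seed(seed, uwot::umap(
          xm, n_components = K, n_threads = 1))
      })
    score <- if (is.null(emb)) NA_real_ else evaluate_embedding(emb, truth, seed)
    data.frame(method = m, K = K, seed = seed, nmi = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("baseline_table", "data.frame")
  out
}

#' @export
print.baseline_table <- function(x, ...) {
  y <- x
  y$nmi <- ifelse(is.na(y$nmi), "N/A", formatC(y$nmi, digits = 4, format = "f"))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
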