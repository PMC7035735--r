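#' Specification of a synthetic ZINB dataset with planted clusters
#'
#' Describes the generative model the autoencoder itself assumes: every
#' cell belongs to one of `n_clusters` clusters; counts for a cell in
#' cluster c are drawn independently per gene from a zero-inflated negative
#' binomial with mean `mean_profiles[c, g]`, shared inverse-dispersion
#' `dispersion`, and dropout probability `dropout` (with probability
#' `dropout` the count is zeroed, otherwise it is a negative binomial draw
#' with variance `mu + mu^2 / theta`).
#'
#' @param n_cells,n_genes,n_clusters Positive integers.
#' @param cluster_proportions Simplex vector of length `n_clusters`
#'   (default uniform).
#' @param mean_profiles `n_clusters x n_genes` matrix of positive NB means;
#'   defaults to block marker profiles from [make_cluster_profiles()].
#' @param dispersion Positive shared inverse-dispersion theta; may also be a
#'   length-`n_genes` vector for per-gene overrides.
#' @param dropout Dropout (zero-inflation) probability in `[0, 1]`; scalar
#'   or length-`n_genes`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells, n_genes, n_clusters,
                           cluster_proportions = NULL,
                           mean_profiles = NULL,
                           dispersion = 2, dropout = 0.3, seed = 0) {
  if (n_cells < 1 || n_genes < 1 || n_clusters < 1) {
    stop("'n_cells', 'n_genes' and 'n_clusters' must be positive", call. = FALSE)
  }
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  }
  if (length(cluster_proportions) != n_clusters ||
      abs(sum(cluster_proportions) - 1) > 1e-9 || any(cluster_proportions < 0)) {
    stop("'cluster_proportions' must be a simplex vector of length n_clusters",
         call. = FALSE)
  }
  if (is.null(mean_profiles)) {
    mean_profiles <- make_cluster_profiles(n_clusters, n_genes)
  }
  mean_profiles <- as.matrix(mean_profiles)
  if (!all(dim(mean_profiles) == c(n_clusters, n_genes)) || any(mean_profiles <= 0)) {
    stop("'mean_profiles' must be a positive n_clusters x n_genes matrix",
         call. = FALSE)
  }
  if (any(dispersion <= 0)) stop("'dispersion' must be positive", call. = FALSE)
  if (any(dropout < 0) || any(dropout > 1)) {
    stop("'dropout' must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 mean_profiles = mean_profiles,
                 dispersion = dispersion, dropout = dropout,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Block marker mean profiles
#'
#' Builds per-cluster NB mean profiles with marker-gene structure: genes are
#' divided into `n_clusters` contiguous blocks; a cluster's block is
#' expressed at `marker_mean` and everything else at `base_mean`, the
#' simplest caricature of cell-type-specific expression programs.
#'
#' @param n_clusters,n_genes Positive integers.
#' @param base_mean,marker_mean Positive background and marker means
#'   (defaults 0.5 and 10 counts).
#' @return `n_clusters x n_genes` matrix of positive means.
#' @export
make_cluster_profiles <- function(n_clusters, n_genes, base_mean = 0.5,
                                  marker_mean = 10) {
  prof <- matrix(base_mean, n_clusters, n_genes)
  block <- floor(n_genes / n_clusters)
  for (c in seq_len(n_clusters)) {
    lo <- (c - 1) * block + 1
    hi <- if (c == n_clusters) n_genes else c * block
    prof[c, lo:hi] <- marker_mean
  }
  prof
}

#' Generate a ZINB count matrix with planted cluster labels
#'
#' Inverts the model the autoencoder assumes: assigns each cell to a
#' cluster by `cluster_proportions`, then draws each count from
#' `ZINB(mu[cluster, gene], theta, pi)`. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (a [count_matrix()]) and `labels`
#'   (integer cluster ids, length `n_cells`).
#' @export
generate_zinb_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_local_seed(spec$seed, {
    labels <- sample.int(spec$n_clusters, spec$n_cells, replace = TRUE,
                         prob = spec$cluster_proportions)
    mu <- spec$mean_profiles[labels, , drop = FALSE]
    theta <- matrix(spec$dispersion, spec$n_cells, spec$n_genes, byrow = TRUE)
    n <- spec$n_cells * spec$n_genes
    counts <- matrix(stats::rnbinom(n, size = theta, mu = mu),
                     spec$n_cells, spec$n_genes)
    pi <- matrix(spec$dropout, spec$n_cells, spec$n_genes, byrow = TRUE)
    keep <- matrix(stats::rbinom(n, 1, 1 - pi), spec$n_cells, spec$n_genes)
    counts <- counts * keep
    list(counts = count_matrix(counts), labels = labels)
  })
}
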