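test_that("NMI matches the contingency-table definition", {
  expect_equal(nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  # independent 2x2 design
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # hand-checked asymmetric case: MI = 0.215761 nats, H(X) = ln 2,
  # H(Y) = 0.562335 nats; brute-force oracle gives the exact value
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 0)), 0.3456, tolerance = 1e-4)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 0, 1, 0)),
               nmi_oracle(c(0, 0, 1, 1), c(0, 0, 1, 0)), tolerance = 1e-12)
  expect_error(nmi(1:3, 1:4), "equal length")
  expect_warning(out <- nmi(c(1, 1), c(1, 2)), "degenerate")
  expect_equal(out, 0)
})

test_that("NMI agrees with a brute-force oracle on random label pairs", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(4:30, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(nmi(x, y), nmi_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("NMI is symmetric, bounded, and invariant to relabeling and base", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    v <- nmi(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, nmi(y, x), tolerance = 1e-12)
    # relabeling either side
    expect_equal(v, nmi(c("u", "v", "w")[x], y), tolerance = 1e-12)
    # the log base cancels in the ratio
    expect_equal(v, nmi_oracle(x, y, base = 2), tolerance = 1e-10)
  }
})

test_that("k-means recovers well-separated planted blobs", {
  set.seed(43)
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  x <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(100, sd = 0.1), 50, 2), 2, centers[k, ], "+")
  }))
  truth <- rep(1:3, each = 50)
  cl <- kmeans_cluster(x, 3, seed = 0)
  expect_equal(nmi(cl$assignments, truth), 1)
  expect_identical(kmeans_cluster(x, 3, seed = 0)$assignments, cl$assignments)
  # degenerate k
  expect_equal(unique(kmeans_cluster(x, 1, seed = 0)$assignments), 1L)
  tiny <- matrix(c(0, 1, 2, 3), 2, 2)
  fit <- kmeans_cluster(tiny, 2, seed = 0)
  expect_equal(fit$inertia, 0)
  expect_error(kmeans_cluster(tiny, 3, seed = 0), "exceeds")
})

test_that("evaluate_embedding composes k-means and NMI", {
  set.seed(44)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(80, sd = 0.1), 40, 2), 2, centers[k, ], "+")
  }))
  truth <- rep(c("a", "b", "c"), each = 40)
  expect_equal(evaluate_embedding(x, truth, seed = 0), 1)
  # invariant to cell order
  perm <- sample(120)
  expect_equal(evaluate_embedding(x[perm, ], truth[perm], seed = 0), 1)
  # invariant to orthogonal rotation
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(evaluate_embedding(x %*% rot, truth, seed = 0), 1)
  expect_error(evaluate_embedding(x, rep("a", 120)), "two classes")
})

test_that("baseline harness embeds with PCA and reports N/A where due", {
  set.seed(45)
  fix <- tiny_data(n_cells = 90, n_genes = 30, seed = 2)
  tab <- run_baselines(fix$proc, methods = c("pca", "tsne"), K = 2,
                       truth = fix$labels, seed = 0)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("method", "K", "seed", "nmi") %in% names(tab)))
  expect_false(is.na(tab$nmi[tab$method == "pca"]))
  # t-SNE cannot embed above 3 dimensions: recorded as N/A, not an error
  tab10 <- run_baselines(fix$proc, methods = "tsne", K = 10,
                         truth = fix$labels, seed = 0)
  expect_true(is.na(tab10$nmi))
  expect_output(print(tab10), "N/A")
})

test_that("PCA baseline solves the planted three-blob problem", {
  set.seed(46)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  base <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(100, sd = 0.1), 50, 2), 2, centers[k, ], "+")
  }))
  # embed the blobs in 6-D with noise so PCA has work to do
  x <- cbind(base, matrix(rnorm(150 * 4, sd = 0.05), 150, 4))
  truth <- rep(1:3, each = 50)
  tab <- run_baselines(x, methods = "pca", K = 2, truth = truth, seed = 0)
  expect_equal(tab$nmi, 1)
})
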