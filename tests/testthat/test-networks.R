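test_that("network_spec enforces the architecture grid", {
  expect_error(network_spec(c(8, 8, 8, 8, 8)), "between 1 and 4")
  expect_error(network_spec(100), "8, 16, 32")
  expect_silent(network_spec(100, allow_any_sizes = TRUE))
  expect_error(network_spec(8, leaky_slope = 0), "leaky_slope")
  expect_error(network_spec(8, dropout_rate = 1), "dropout_rate")
})

test_that("encoder produces well-shaped deterministic posterior parameters", {
  set.seed(1)
  enc <- make_encoder(12, 3, network_spec(c(16, 8)))
  x <- matrix(rnorm(5 * 12), 5, 12)
  out <- encode(enc, x)
  expect_equal(dim(out$mean), c(5L, 3L))
  expect_equal(dim(out$log_variance), c(5L, 3L))
  # inference determinism
  expect_identical(out, encode(enc, x))
  expect_error(encode(enc, matrix(0, 2, 5)), "width")
})

test_that("zeroed encoder weights give zero mean and log-variance", {
  set.seed(1)
  enc <- make_encoder(6, 2, network_spec(8))
  enc$trunk$W <- lapply(enc$trunk$W, function(w) w * 0)
  enc$trunk$b <- lapply(enc$trunk$b, function(b) b * 0)
  enc$head_mean$W <- enc$head_mean$W * 0
  enc$head_logvar$W <- enc$head_logvar$W * 0
  out <- encode(enc, matrix(rnorm(12), 2, 6))
  expect_true(all(out$mean == 0))
  expect_true(all(out$log_variance == 0))
})

test_that("reparameterization is the location-scale transform", {
  out <- list(mean = matrix(1:6, 2, 3), log_variance = matrix(0, 2, 3))
  # zero noise returns the mean
  expect_equal(reparameterize(out, matrix(0, 2, 3)), out$mean)
  # unit variance shifts by the noise
  eps <- matrix(rnorm(6), 2, 3)
  expect_equal(reparameterize(out, eps), out$mean + eps, tolerance = 1e-12)
  # scale: log-variance log(4) doubles the noise
  out$log_variance <- matrix(log(4), 2, 3)
  expect_equal(reparameterize(out, eps), out$mean + 2 * eps, tolerance = 1e-12)
})

test_that("decoder always emits valid ZINB parameters", {
  set.seed(2)
  dec <- make_decoder(2, 9, network_spec(c(16, 16)))
  for (i in 1:20) {
    z <- matrix(rnorm(8, sd = 10^runif(1, -1, 2)), 4, 2)
    p <- decode(dec, z)
    expect_true(all(p$mu > 0) && all(p$theta > 0))
    expect_true(all(p$pi > 0) && all(p$pi < 1))
    expect_true(all(vapply(p, function(m) all(is.finite(m)), TRUE)))
    expect_equal(unname(vapply(p, dim, c(1L, 1L))[1, ]), rep(4L, 3))
    expect_equal(unname(vapply(p, dim, c(1L, 1L))[2, ]), rep(9L, 3))
  }
  expect_identical(decode(dec, matrix(0.3, 2, 2)), decode(dec, matrix(0.3, 2, 2)))
  expect_error(decode(dec, matrix(c(1, NA), 1, 2)), "finite")
})

test_that("discriminator scores respect the domain", {
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4)
  dp <- make_discriminator(4, network_spec(8), "probability")
  sp <- discriminate(dp, x)
  expect_true(all(sp > 0 & sp < 1))
  du <- make_discriminator(4, network_spec(8), "unbounded")
  expect_true(all(is.finite(discriminate(du, x))))
  # batch scoring equals per-sample scoring
  one_by_one <- vapply(1:10, function(i) discriminate(dp, x[i, , drop = FALSE]), 0)
  expect_equal(sp, one_by_one, tolerance = 1e-12)
  expect_error(discriminate(dp, matrix(0, 2, 3)), "width")
  # aliases for the two roles
  expect_equal(discriminate_latent(dp, x), sp)
  expect_equal(discriminate_data(dp, x), sp)
})

test_that("prior samples have standard normal moments", {
  z <- sample_prior(200000, 2, seed = 42)
  expect_lt(max(abs(colMeans(z))), 0.01)
  expect_lt(max(abs(stats::cov(z) - diag(2))), 0.02)
  expect_identical(sample_prior(50, 3, seed = 9), sample_prior(50, 3, seed = 9))
})

test_that("MLP backprop matches finite-difference gradients", {
  set.seed(5)
  spec <- network_spec(c(8, 8), dropout_rate = 0)
  net <- scAVAE:::.mlp_new(4, spec)
  x <- matrix(rnorm(12), 3, 4)
  loss <- function(net) {
    fw <- scAVAE:::.mlp_forward(net, x)
    sum(fw$H^2)
  }
  fw <- scAVAE:::.mlp_forward(net, x)
  bk <- scAVAE:::.mlp_backward(net, fw, 2 * fw$H)
  h <- 1e-6
  for (k in 1:2) {
    for (idx in sample(length(net$W[[k]]), 5)) {
      np <- net; nm <- net
      np$W[[k]][idx] <- np$W[[k]][idx] + h
      nm$W[[k]][idx] <- nm$W[[k]][idx] - h
      expect_equal(bk$dW[[k]][idx], (loss(np) - loss(nm)) / (2 * h),
                   tolerance = 1e-4)
    }
  }
  # input gradient
  fdx <- matrix(0, 3, 4)
  for (idx in seq_len(12)) {
    xp <- x; xm <- x
    xp[idx] <- xp[idx] + h; xm[idx] <- xm[idx] - h
    f <- function(xx) sum(scAVAE:::.mlp_forward(net, xx)$H^2)
    fdx[idx] <- (f(xp) - f(xm)) / (2 * h)
  }
  expect_equal(bk$dX, fdx, tolerance = 1e-4)
})

test_that("gradient-penalty double backprop matches finite differences", {
  set.seed(6)
  disc <- make_discriminator(3, network_spec(c(8, 8), dropout_rate = 0),
                             "unbounded")
  xhat <- matrix(rnorm(15), 5, 3)
  res <- scAVAE:::.gp_penalty_and_grads(disc, xhat, weight = 10)
  pen <- function(d) {
    g <- scAVAE:::.disc_input_grad(d, xhat)
    10 * mean((sqrt(rowSums(g^2) + 1e-12) - 1)^2)
  }
  expect_equal(res$penalty, pen(disc), tolerance = 1e-10)
  h <- 1e-6
  for (k in 1:2) {
    for (idx in sample(length(disc$trunk$W[[k]]), 4)) {
      dp <- disc; dm <- disc
      dp$trunk$W[[k]][idx] <- dp$trunk$W[[k]][idx] + h
      dm$trunk$W[[k]][idx] <- dm$trunk$W[[k]][idx] - h
      expect_equal(res$grads$trunk$dW[[k]][idx], (pen(dp) - pen(dm)) / (2 * h),
                   tolerance = 1e-3)
    }
  }
  for (idx in 1:8) {
    dp <- disc; dm <- disc
    dp$head$W[idx] <- dp$head$W[idx] + h
    dm$head$W[idx] <- dm$head$W[idx] - h
    expect_equal(res$grads$head$dW[idx], (pen(dp) - pen(dm)) / (2 * h),
                 tolerance = 1e-3)
  }
})
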