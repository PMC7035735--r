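test_that("standard GAN loss matches the minimax objective values", {
  # indifferent discriminator: D = 1/2 everywhere
  l <- standard_gan_loss(score_batch(c(.5, .5), c(.5, .5)))
  expect_equal(l$discriminator_loss, 2 * log(2), tolerance = 1e-12)
  # direct evaluation
  l <- standard_gan_loss(score_batch(0.8, 0.3))
  expect_equal(l$discriminator_loss, -log(0.8) - log(0.7), tolerance = 1e-12)
  expect_equal(l$generator_loss, -log(0.3), tolerance = 1e-12)
  # a perfect discriminator drives its loss to 0 monotonically
  path <- seq(0.5, 0.999, length.out = 20)
  losses <- vapply(path, function(p) {
    standard_gan_loss(score_batch(p, 1 - p))$discriminator_loss
  }, 0)
  expect_true(all(diff(losses) < 0))
  expect_lt(losses[20], 0.01)
})

test_that("probability-domain scores are validated", {
  expect_error(score_batch(c(0.5, 1.2), 0.5), "strictly in")
  expect_error(score_batch(0, 0.5), "strictly in")
  expect_error(standard_gan_loss(score_batch(1, -1, domain = "unbounded")),
               "probability")
})

test_that("Wasserstein loss is the mean-difference critic objective", {
  expect_equal(wasserstein_loss(score_batch(c(1, 1), c(0, 0),
                                            domain = "unbounded"))$discriminator_loss,
               -1)
  s <- score_batch(c(0.3, -0.2), c(0.3, -0.2), domain = "unbounded")
  expect_equal(wasserstein_loss(s)$discriminator_loss, 0)
  s <- score_batch(c(0.2, 0.6), c(-0.1, 0.3), domain = "unbounded")
  expect_equal(wasserstein_loss(s)$discriminator_loss, -0.3, tolerance = 1e-12)
})

test_that("gradient penalty matches closed-form critics", {
  set.seed(4)
  real <- matrix(rnorm(20), 5, 4)
  fake <- matrix(rnorm(20), 5, 4)
  w <- rnorm(4); w <- w / sqrt(sum(w^2))
  # unit-slope linear critic: zero penalty
  expect_lt(gradient_penalty(function(x) x %*% w, real, fake, weight = 10), 1e-6)
  # constant critic: penalty = weight
  expect_equal(gradient_penalty(function(x) rep(1, nrow(x)), real, fake,
                                weight = 10), 10, tolerance = 1e-6)
  # slope-2 critic: (2 - 1)^2 = 1, penalty = weight
  expect_equal(gradient_penalty(function(x) 2 * (x %*% w), real, fake,
                                weight = 7), 7, tolerance = 1e-5)
})

test_that("discrete Bhattacharyya distance matches direct summation", {
  p <- c(0.2, 0.5, 0.3)
  expect_equal(bhattacharyya_discrete(p, p), 0, tolerance = 1e-12)
  expect_equal(bhattacharyya_discrete(c(1, 0), c(0, 1)), Inf)
  expect_equal(bhattacharyya_discrete(c(0.5, 0.5), c(0.9, 0.1)),
               -log(sqrt(0.45) + sqrt(0.05)), tolerance = 1e-12)
  expect_error(bhattacharyya_discrete(c(0.5, 0.5), c(0.5, 0.4)), "sum to 1")
  expect_error(bhattacharyya_discrete(c(0.5, 0.5), c(1)), "equal length")
})

test_that("discrete BD is nonnegative and zero only at equality", {
  set.seed(8)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    p <- as.numeric(rmultinom(1, 500, runif(k))) / 500
    q <- as.numeric(rmultinom(1, 500, runif(k))) / 500
    bd <- bhattacharyya_discrete(p, q)
    expect_gte(bd, 0)
    if (max(abs(p - q)) > 1e-6) expect_gt(bd, 0)
  }
})

test_that("Gaussian BD closed form agrees with numeric integration", {
  expect_equal(bhattacharyya_gaussian(0, 1, 0, 1), 0)
  expect_equal(bhattacharyya_gaussian(0, 1, 1, 1), 0.125, tolerance = 1e-12)
  set.seed(17)
  for (i in 1:100) {
    m1 <- rnorm(1); m2 <- rnorm(1)
    v1 <- runif(1, 0.2, 3); v2 <- runif(1, 0.2, 3)
    num <- -log(stats::integrate(function(x) {
      sqrt(stats::dnorm(x, m1, sqrt(v1)) * stats::dnorm(x, m2, sqrt(v2)))
    }, -Inf, Inf, rel.tol = 1e-10)$value)
    closed <- bhattacharyya_gaussian(m1, v1, m2, v2)
    expect_equal(closed, num, tolerance = 1e-6)
    # symmetry
    expect_equal(closed, bhattacharyya_gaussian(m2, v2, m1, v1),
                 tolerance = 1e-12)
  }
})

test_that("BD adversarial loss moment-matches score batches", {
  # identical batches: both losses zero
  s <- score_batch(c(0.4, 0.6), c(0.4, 0.6))
  l <- bd_adversarial_loss(s)
  expect_equal(l$discriminator_loss, 0, tolerance = 1e-12)
  expect_equal(l$generator_loss, 0, tolerance = 1e-12)
  # hand-evaluated closed form: N(0.85, 0.0025) vs N(0.15, 0.0025)
  l <- bd_adversarial_loss(score_batch(c(0.9, 0.8), c(0.1, 0.2)))
  expect_equal(l$discriminator_loss, -24.5, tolerance = 1e-10)
  # swapping real and fake leaves the magnitude unchanged
  l2 <- bd_adversarial_loss(score_batch(c(0.1, 0.2), c(0.9, 0.8)))
  expect_equal(abs(l2$discriminator_loss), abs(l$discriminator_loss),
               tolerance = 1e-12)
  expect_error(bd_adversarial_loss(score_batch(0.5, c(0.4, 0.6))), "at least 2")
})

test_that("all objectives stay finite on random valid score batches", {
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(2:8, 1)
    sp <- score_batch(runif(n, 0.01, 0.99), runif(n, 0.01, 0.99))
    su <- score_batch(rnorm(n, sd = 3), rnorm(n, sd = 3), domain = "unbounded")
    for (obj in c("standard", "bhattacharyya")) {
      l <- adversarial_loss(sp, obj)
      expect_true(is.finite(l$discriminator_loss) && is.finite(l$generator_loss))
    }
    for (obj in c("wasserstein", "wasserstein_gp")) {
      l <- adversarial_loss(su, obj)
      expect_true(is.finite(l$discriminator_loss) && is.finite(l$generator_loss))
    }
  }
})

test_that("BD adversarial analytic score gradients match finite differences", {
  set.seed(31)
  r <- runif(5, 0.2, 0.8); f <- runif(5, 0.2, 0.8)
  g <- scAVAE:::.bd_grads(score_batch(r, f))
  h <- 1e-7
  dl <- function(r, f) bd_adversarial_loss(score_batch(r, f))$discriminator_loss
  gl <- function(r, f) bd_adversarial_loss(score_batch(r, f))$generator_loss
  for (i in 1:5) {
    rp <- r; rm <- r; rp[i] <- rp[i] + h; rm[i] <- rm[i] - h
    expect_equal(g$d_disc_real[i], (dl(rp, f) - dl(rm, f)) / (2 * h),
                 tolerance = 1e-4)
    fp <- f; fm <- f; fp[i] <- fp[i] + h; fm[i] <- fm[i] - h
    expect_equal(g$d_disc_fake[i], (dl(r, fp) - dl(r, fm)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(g$d_gen_fake[i], (gl(r, fp) - gl(r, fm)) / (2 * h),
                 tolerance = 1e-4)
  }
})
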