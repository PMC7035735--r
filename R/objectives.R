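#' Discriminator score batch
#'
#' Bundles the discriminator outputs on a batch of real samples and a batch
#' of generated samples, together with the score domain. Probability-domain
#' scores (sigmoid head) must lie in (0, 1); unbounded scores (linear head,
#' Wasserstein critics) may be any finite real.
#'
#' @param real_scores,fake_scores Numeric vectors of discriminator outputs.
#' @param domain `"probability"` or `"unbounded"`.
#' @return An object of class `score_batch`.
#' @export
score_batch <- function(real_scores, fake_scores,
                        domain = c("probability", "unbounded")) {
  domain <- match.arg(domain)
  real_scores <- as.numeric(real_scores)
  fake_scores <- as.numeric(fake_scores)
  if (any(!is.finite(real_scores)) || any(!is.finite(fake_scores))) {
    stop("scores must be finite", call. = FALSE)
  }
  if (domain == "probability" &&
    (any(real_scores <= 0) || any(real_scores >= 1) ||
      any(fake_scores <= 0) || any(fake_scores >= 1))) {
    stop("probability-domain scores must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(real_scores = real_scores, fake_scores = fake_scores,
                 domain = domain), class = "score_batch")
}

.as_score_batch <- function(scores, domain) {
  if (!inherits(scores, "score_batch")) {
    stop("'scores' must be a score_batch object", call. = FALSE)
  }
  if (scores$domain != domain) {
    stop(sprintf("this objective requires %s-domain scores", domain), call. = FALSE)
  }
  scores
}

#' Standard (non-saturating) GAN objective
#'
#' Discriminator loss is the negated minimax objective,
#' `-mean(log D(x)) - mean(log(1 - D(G(z))))`; the generator minimizes the
#' non-saturating form `-mean(log D(G(z)))`.
#'
#' @param scores A [score_batch()] in the probability domain.
#' @return List with `discriminator_loss` and `generator_loss`.
#' @examples
#' standard_gan_loss(score_batch(c(.5, .5), c(.5, .5)))$discriminator_loss # 2 log 2
#' @export
standard_gan_loss <- function(scores) {
  s <- .as_score_batch(scores, "probability")
  list(
    discriminator_loss = -mean(log(s$real_scores)) - mean(log1p(-s$fake_scores)),
    generator_loss = -mean(log(s$fake_scores))
  )
}

# d(losses)/d(scores); each term 1/n-scaled like the means above
.standard_gan_grads <- function(scores) {
  nr <- length(scores$real_scores)
  nf <- length(scores$fake_scores)
  list(
    d_disc_real = -1 / (nr * scores$real_scores),
    d_disc_fake = 1 / (nf * (1 - scores$fake_scores)),
    d_gen_fake = -1 / (nf * scores$fake_scores)
  )
}

#' Wasserstein critic objective
#'
#' Critic maximizes `mean(D(x)) - mean(D(G(z)))`; losses are the negations so
#' both players minimize.
#'
#' @param scores A [score_batch()] in the unbounded domain.
#' @return List with `discriminator_loss` and `generator_loss`.
#' @export
wasserstein_loss <- function(scores) {
  s <- .as_score_batch(scores, "unbounded")
  list(
    discriminator_loss = -(mean(s$real_scores) - mean(s$fake_scores)),
    generator_loss = -mean(s$fake_scores)
  )
}

.wasserstein_grads <- function(scores) {
  nr <- length(scores$real_scores)
  nf <- length(scores$fake_scores)
  list(
    d_disc_real = rep(-1 / nr, nr),
    d_disc_fake = rep(1 / nf, nf),
    d_gen_fake = rep(-1 / nf, nf)
  )
}

#' Gradient penalty for a Wasserstein critic
#'
#' Soft Lipschitz constraint of the WGAN-GP scheme: sample
#' `xhat = eps * x_real + (1 - eps) * x_fake` with `eps ~ U(0,1)` per row and
#' penalize `weight * mean((||grad_xhat D(xhat)||_2 - 1)^2)`.
#'
#' @param score_fn Either a discriminator object created by
#'   [make_discriminator()] (analytic input gradients) or a function mapping
#'   an `n x d` matrix to `n` scores (central finite differences are used).
#' @param real,fake Matrices of equal dimension (`n x d`).
#' @param weight Positive penalty coefficient (default 10).
#' @param grad_fn Optional function returning the `n x d` input gradient of
#'   `score_fn`, bypassing finite differences.
#' @return The scalar penalty (non-negative).
#' @export
gradient_penalty <- function(score_fn, real, fake, weight = 10, grad_fn = NULL) {
  real <- as.matrix(real)
  fake <- as.matrix(fake)
  if (!all(dim(real) == dim(fake))) {
    stop("'real' and 'fake' must have identical dimensions", call. = FALSE)
  }
  if (weight <= 0) stop("'weight' must be positive", call. = FALSE)
  eps <- stats::runif(nrow(real))
  xhat <- eps * real + (1 - eps) * fake
  if (inherits(score_fn, "avae_discriminator")) {
    g <- .disc_input_grad(score_fn, xhat)
  } else if (!is.null(grad_fn)) {
    g <- as.matrix(grad_fn(xhat))
  } else {
    g <- .fd_input_grad(score_fn, xhat)
  }
  norms <- sqrt(rowSums(g^2))
  weight * mean((norms - 1)^2)
}

.fd_input_grad <- function(f, x, h = 1e-5) {
  g <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(ncol(x))) {
    xp <- x; xm <- x
    xp[, j] <- xp[, j] + h
    xm[, j] <- xm[, j] - h
    g[, j] <- (as.numeric(f(xp)) - as.numeric(f(xm))) / (2 * h)
  }
  g
}

#' Bhattacharyya distance between two discrete distributions
#'
#' `BD(p, q) = -ln(sum(sqrt(p * q)))`; zero iff `p == q`, `+Inf` for disjoint
#' supports.
#'
#' @param p,q Probability vectors of equal length, each summing to 1.
#' @return Non-negative scalar (possibly `Inf`).
#' @export
bhattacharyya_discrete <- function(p, q) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("'p' and 'q' must each sum to 1", call. = FALSE)
  }
  -log(sum(sqrt(p * q)))
}

#' Bhattacharyya distance between two univariate Gaussians
#'
#' Closed form:
#' \deqn{BD = \frac{(\mu_1-\mu_2)^2}{4(\sigma_1^2+\sigma_2^2)} +
#'   \frac{1}{2}\ln\frac{\sigma_1^2+\sigma_2^2}{2\sigma_1\sigma_2}}
#'
#' @param mean1,mean2 Means.
#' @param var1,var2 Positive variances.
#' @return Non-negative scalar.
#' @export
bhattacharyya_gaussian <- function(mean1, var1, mean2, var2) {
  if (any(var1 <= 0) || any(var2 <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  vs <- var1 + var2
  0.25 * (mean1 - mean2)^2 / vs + 0.5 * log(vs / (2 * sqrt(var1 * var2)))
}

#' Bhattacharyya-distance adversarial objective
#'
#' The objective that defines the AVAE-DM default: fit a Gaussian to the
#' real-score batch and to the fake-score batch by moment matching
#' (sample mean, population variance floored at 1e-6) and use their
#' Bhattacharyya distance. The discriminator maximizes the separation
#' (loss `-BD`); the generator minimizes it, with the real-score moments
#' held constant.
#'
#' @param scores A [score_batch()] in the probability domain with at least
#'   two scores on each side.
#' @return List with `discriminator_loss` and `generator_loss`.
#' @export
bd_adversarial_loss <- function(scores) {
  s <- .as_score_batch(scores, "probability")
  if (length(s$real_scores) < 2 || length(s$fake_scores) < 2) {
    stop("the Bhattacharyya objective needs at least 2 scores per batch", call. = FALSE)
  }
  mr <- mean(s$real_scores)
  mf <- mean(s$fake_scores)
  vr <- max(.pop_var(s$real_scores), 1e-6)
  vf <- max(.pop_var(s$fake_scores), 1e-6)
  bd <- bhattacharyya_gaussian(mr, vr, mf, vf)
  list(discriminator_loss = -bd, generator_loss = bd)
}

.pop_var <- function(x) mean((x - mean(x))^2)

# Gradients of BD(N(mr,vr), N(mf,vf)) wrt the raw scores, with the variance
# floor zeroing the variance path when active.
.bd_grads <- function(scores) {
  r <- scores$real_scores
  f <- scores$fake_scores
  nr <- length(r); nf <- length(f)
  mr <- mean(r); mf <- mean(f)
  vr0 <- .pop_var(r); vf0 <- .pop_var(f)
  vr <- max(vr0, 1e-6); vf <- max(vf0, 1e-6)
  vs <- vr + vf
  dBD_dmr <- 0.5 * (mr - mf) / vs
  dBD_dmf <- -dBD_dmr
  dBD_dvr <- -0.25 * (mr - mf)^2 / vs^2 + 0.5 * (1 / vs - 1 / (2 * vr))
  dBD_dvf <- -0.25 * (mr - mf)^2 / vs^2 + 0.5 * (1 / vs - 1 / (2 * vf))
  dvr_ds <- if (vr0 >= 1e-6) 2 * (r - mr) / nr else rep(0, nr)
  dvf_ds <- if (vf0 >= 1e-6) 2 * (f - mf) / nf else rep(0, nf)
  dBD_real <- dBD_dmr / nr + dBD_dvr * dvr_ds
  dBD_fake <- dBD_dmf / nf + dBD_dvf * dvf_ds
  # discriminator loss = -BD (through both batches); generator loss = +BD
  # (real moments constant)
  list(
    d_disc_real = -dBD_real,
    d_disc_fake = -dBD_fake,
    d_gen_fake = dBD_fake
  )
}

#' Adversarial objective dispatcher
#'
#' Maps an objective token to its loss pair. Tokens: `"standard"`,
#' `"wasserstein"`, `"wasserstein_gp"` (same losses as `"wasserstein"`, the
#' penalty is added separately during training), `"bhattacharyya"` (the
#' AVAE-DM default).
#'
#' @param scores A [score_batch()].
#' @param objective Objective token.
#' @return List with `discriminator_loss` and `generator_loss`.
#' @export
adversarial_loss <- function(scores,
                             objective = c("bhattacharyya", "standard",
                                           "wasserstein", "wasserstein_gp")) {
  objective <- match.arg(objective)
  switch(objective,
    standard = standard_gan_loss(scores),
    wasserstein = wasserstein_loss(scores),
    wasserstein_gp = wasserstein_loss(scores),
    bhattacharyya = bd_adversarial_loss(scores)
  )
}

.objective_domain <- function(objective) {
  if (objective %in% c("wasserstein", "wasserstein_gp")) "unbounded" else "probability"
}

.adversarial_grads <- function(scores, objective) {
  switch(objective,
    standard = .standard_gan_grads(scores),
    wasserstein = .wasserstein_grads(scores),
    wasserstein_gp = .wasserstein_grads(scores),
    bhattacharyya = .bd_grads(scores)
  )
}
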