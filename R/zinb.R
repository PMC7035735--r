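#' Negative binomial log-probability mass function
#'
#' Mean--dispersion parameterization: `NB(x; mu, theta)` has mean `mu` and
#' variance `mu + mu^2 / theta`, i.e. `theta` is the inverse-dispersion
#' ("size"). Computed entirely in log space:
#' \deqn{\ln NB(x) = \ln\Gamma(x+\theta) - \ln\Gamma(\theta) - \ln\Gamma(x+1)
#'   + \theta \ln\frac{\theta}{\theta+\mu} + x \ln\frac{\mu}{\theta+\mu}}
#'
#' @param x Non-negative integer counts (vector/matrix, recycled against
#'   `mu`/`theta`).
#' @param mu Positive NB mean.
#' @param theta Positive inverse-dispersion.
#' @return Log pmf values, same shape as the broadcast of the inputs.
#' @examples
#' nb_log_pmf(0, mu = 2, theta = 1) # log(1/3)
#' @export
nb_log_pmf <- function(x, mu, theta) {
  .check_counts(x)
  if (any(mu <= 0) || any(!is.finite(mu))) {
    stop("'mu' must be positive and finite", call. = FALSE)
  }
  if (any(theta <= 0) || any(!is.finite(theta))) {
    stop("'theta' must be positive and finite", call. = FALSE)
  }
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial log-probability mass function
#'
#' Mixture of a point mass at zero (weight `pi`) and `NB(mu, theta)`:
#' zeros have probability `pi + (1 - pi) NB(0)`, positive counts
#' `(1 - pi) NB(x)`. The zero branch is evaluated with log-sum-exp
#' stability.
#'
#' @inheritParams nb_log_pmf
#' @param pi Zero-inflation (dropout) probability in `[0, 1]`.
#' @return Log pmf values.
#' @examples
#' zinb_log_pmf(0, mu = 2, theta = 1, pi = 0.5) # log(2/3)
#' @export
zinb_log_pmf <- function(x, mu, theta, pi) {
  if (any(pi < 0) || any(pi > 1) || any(!is.finite(pi))) {
    stop("'pi' must lie in [0, 1]", call. = FALSE)
  }
  nb <- nb_log_pmf(x, mu, theta)
  # recycle pi to the shape of nb
  pib <- pi + 0 * nb
  out <- log1p(-pib) + nb
  zero <- (x + 0 * nb) == 0
  if (any(zero)) {
    # log(pi + (1-pi) * nb0) via log-sum-exp of [log(pi), log1p(-pi) + nb0]
    lp <- log(pib[zero])
    lq <- out[zero]
    m <- pmax(lp, lq)
    m[!is.finite(m)] <- 0 # pi = 0 gives lp = -Inf; lq is then the answer
    out[zero] <- ifelse(pib[zero] == 0, lq,
      ifelse(pib[zero] == 1, 0, m + log(exp(lp - m) + exp(lq - m)))
    )
  }
  out
}

#' ZINB reconstruction loss (negative log-likelihood per cell)
#'
#' The decoder's training loss: minus the ZINB log-likelihood of a batch of
#' raw counts, summed over genes and averaged over cells. Parameters are
#' clamped away from the boundary (`mu`, `theta` at 1e-8; `pi` inside
#' `[1e-8, 1-1e-8]`) so the loss stays finite during optimization.
#'
#' @param x `M x G` matrix of non-negative integer counts.
#' @param mu,theta,pi ZINB parameters, each a scalar, length-`G` vector, or
#'   `M x G` matrix (broadcast over cells).
#' @return A single non-negative number.
#' @export
zinb_reconstruction_loss <- function(x, mu, theta, pi) {
  x <- as.matrix(x)
  m <- nrow(x)
  g <- ncol(x)
  bc <- function(p, name) {
    if (length(p) == 1) p <- matrix(p, m, g)
    else if (is.null(dim(p)) && length(p) == g) p <- matrix(p, m, g, byrow = TRUE)
    else if (is.matrix(p) && all(dim(p) == c(m, g))) p <- p
    else stop(sprintf("'%s' is not broadcastable to %d x %d", name, m, g), call. = FALSE)
    p
  }
  mu <- pmax(bc(mu, "mu"), 1e-8)
  theta <- pmax(bc(theta, "theta"), 1e-8)
  pi <- pmin(pmax(bc(pi, "pi"), 1e-8), 1 - 1e-8)
  -sum(zinb_log_pmf(x, mu, theta, pi)) / m
}

# Gradients of the summed ZINB NLL wrt (mu, theta, pi), divided by the cell
# count, for full M x G matrices. Used by the training loop; kept internal.
.zinb_nll_grads <- function(x, mu, theta, pi) {
  m <- nrow(x)
  tm <- theta + mu
  nb0_log <- theta * (log(theta) - log(tm)) # log NB(0)
  nb0 <- exp(nb0_log)
  denom0 <- pi + (1 - pi) * nb0
  zero <- x == 0

  dmu <- x / mu - (x + theta) / tm # positive branch d logpmf / dmu
  dth <- digamma(x + theta) - digamma(theta) +
    log(theta) - log(tm) + (mu - x) / tm
  dpi <- -1 / (1 - pi)

  dmu0 <- -(1 - pi) * nb0 * theta / (tm * denom0)
  dth0 <- (1 - pi) * nb0 * (log(theta) - log(tm) + mu / tm) / denom0
  dpi0 <- (1 - nb0) / denom0

  dmu[zero] <- dmu0[zero]
  dth[zero] <- dth0[zero]
  dpi[zero] <- dpi0[zero]
  # NLL = -(1/m) * sum(logpmf)
  list(dmu = -dmu / m, dtheta = -dth / m, dpi = -dpi / m)
}

.check_counts <- function(x, what = "x") {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x))) {
    stop(sprintf("'%s' must contain non-negative integers", what), call. = FALSE)
  }
  invisible(TRUE)
}
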