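#' Fully connected network specification
#'
#' The architecture grid used throughout: 1--4 hidden layers, each drawn
#' from {8, 16, 32, 64, 128, 256, 512, 1024} nodes, LeakyReLU activations
#' between hidden layers, and dropout regularization on hidden layers.
#'
#' @param layer_sizes Integer vector of hidden-layer widths (length 1--4).
#' @param leaky_slope Negative slope of the LeakyReLU (default 0.2).
#' @param dropout_rate Hidden-layer dropout probability in `[0, 1)`
#'   (default 0.1); applied at training time only.
#' @param allow_any_sizes Set `TRUE` to bypass the width grid (e.g. for
#'   small unit-test networks).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes, leaky_slope = 0.2, dropout_rate = 0.1,
                         allow_any_sizes = FALSE) {
  layer_sizes <- as.integer(layer_sizes)
  allowed <- c(8L, 16L, 32L, 64L, 128L, 256L, 512L, 1024L)
  if (length(layer_sizes) < 1 || length(layer_sizes) > 4) {
    stop("'layer_sizes' must have between 1 and 4 entries", call. = FALSE)
  }
  if (!allow_any_sizes && !all(layer_sizes %in% allowed)) {
    stop("layer sizes must be one of 8, 16, 32, 64, 128, 256, 512, 1024 ",
         "(or set allow_any_sizes = TRUE)", call. = FALSE)
  }
  if (any(layer_sizes < 1)) stop("layer sizes must be positive", call. = FALSE)
  if (leaky_slope <= 0) stop("'leaky_slope' must be positive", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("'dropout_rate' must lie in [0, 1)", call. = FALSE)
  }
  structure(list(layer_sizes = layer_sizes, leaky_slope = leaky_slope,
                 dropout_rate = dropout_rate), class = "network_spec")
}

# ---- internal MLP machinery ------------------------------------------------

# He-style Gaussian init; draws from the current RNG stream so a single
# set.seed() upstream makes whole-model construction reproducible.
.mlp_new <- function(d_in, spec) {
  sizes <- c(d_in, spec$layer_sizes)
  W <- vector("list", length(spec$layer_sizes))
  b <- vector("list", length(spec$layer_sizes))
  for (k in seq_along(W)) {
    W[[k]] <- matrix(stats::rnorm(sizes[k] * sizes[k + 1], sd = sqrt(2 / sizes[k])),
                     sizes[k], sizes[k + 1])
    b[[k]] <- numeric(sizes[k + 1])
  }
  list(W = W, b = b, slope = spec$leaky_slope, dropout = spec$dropout_rate,
       d_in = d_in)
}

.linear_new <- function(d_in, d_out, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(1 / d_in)
  list(W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
       b = numeric(d_out))
}

.leaky <- function(a, slope) ifelse(a > 0, a, slope * a)

# Forward pass; returns final hidden activations and the caches needed for
# backprop (pre-activations and dropout masks).
.mlp_forward <- function(net, X, train = FALSE) {
  H <- X
  A <- vector("list", length(net$W))
  masks <- vector("list", length(net$W))
  for (k in seq_along(net$W)) {
    A[[k]] <- sweep(H %*% net$W[[k]], 2, net$b[[k]], "+")
    H <- .leaky(A[[k]], net$slope)
    if (train && net$dropout > 0) {
      m <- matrix(stats::rbinom(length(H), 1, 1 - net$dropout), nrow(H)) /
        (1 - net$dropout)
      H <- H * m
      masks[[k]] <- m
    } else {
      masks[[k]] <- 1
    }
  }
  # cache hidden inputs to each layer for weight grads
  list(H = H, A = A, masks = masks, X = X)
}

# dH: gradient wrt the final (post-dropout) hidden output.
.mlp_backward <- function(net, fw, dH) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  # reconstruct layer inputs
  ins <- vector("list", L)
  H <- fw$X
  for (k in seq_len(L)) {
    ins[[k]] <- H
    H <- .leaky(fw$A[[k]], net$slope) * fw$masks[[k]]
  }
  d <- dH
  for (k in rev(seq_len(L))) {
    d <- d * fw$masks[[k]]
    d <- d * ifelse(fw$A[[k]] > 0, 1, net$slope)
    dW[[k]] <- crossprod(ins[[k]], d)
    db[[k]] <- colSums(d)
    d <- tcrossprod(d, net$W[[k]])
  }
  list(dW = dW, db = db, dX = d)
}

.linear_forward <- function(lin, H) sweep(H %*% lin$W, 2, lin$b, "+")

.linear_backward <- function(lin, H, dOut) {
  list(dW = crossprod(H, dOut), db = colSums(dOut), dH = tcrossprod(dOut, lin$W))
}

# ---- encoder ---------------------------------------------------------------

#' Build a variational encoder
#'
#' MLP trunk followed by two linear heads giving the mean and log-variance
#' of the diagonal-Gaussian variational posterior q(z|x).
#'
#' @param d_in Input width (number of selected genes G).
#' @param latent_dim Latent dimension K.
#' @param spec A [network_spec()].
#' @return An object of class `avae_encoder`.
#' @export
make_encoder <- function(d_in, latent_dim, spec) {
  trunk <- .mlp_new(d_in, spec)
  h <- utils::tail(spec$layer_sizes, 1)
  structure(list(trunk = trunk, head_mean = .linear_new(h, latent_dim),
                 head_logvar = .linear_new(h, latent_dim),
                 d_in = d_in, latent_dim = latent_dim, spec = spec),
            class = "avae_encoder")
}

#' Encode expression vectors to posterior parameters
#'
#' @param encoder An [make_encoder()] object.
#' @param x `n x G` matrix of (log-transformed) expression values.
#' @param train Logical; enable dropout (training mode). Inference is
#'   deterministic.
#' @return List with `mean` and `log_variance` (`n x K` each).
#' @export
encode <- function(encoder, x, train = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != encoder$d_in) {
    stop(sprintf("input width %d does not match encoder width %d",
                 ncol(x), encoder$d_in), call. = FALSE)
  }
  fw <- .mlp_forward(encoder$trunk, x, train = train)
  list(mean = .linear_forward(encoder$head_mean, fw$H),
       log_variance = .linear_forward(encoder$head_logvar, fw$H))
}

.encode_full <- function(encoder, x, train = FALSE) {
  fw <- .mlp_forward(encoder$trunk, x, train = train)
  list(fw = fw,
       mean = .linear_forward(encoder$head_mean, fw$H),
       log_variance = .linear_forward(encoder$head_logvar, fw$H))
}

.encoder_backward <- function(encoder, full, dmean, dlogvar) {
  g1 <- .linear_backward(encoder$head_mean, full$fw$H, dmean)
  g2 <- .linear_backward(encoder$head_logvar, full$fw$H, dlogvar)
  gt <- .mlp_backward(encoder$trunk, full$fw, g1$dH + g2$dH)
  list(trunk = gt, head_mean = g1, head_logvar = g2)
}

#' Reparameterization trick
#'
#' `z = mean + exp(0.5 * log_variance) * noise` with standard-normal noise,
#' making the sampling step differentiable in the posterior parameters.
#'
#' @param out List with `mean` and `log_variance` (as returned by [encode()]).
#' @param noise Matrix of standard normal draws, same shape as `out$mean`;
#'   drawn internally when `NULL`.
#' @return `n x K` matrix of latent codes.
#' @export
reparameterize <- function(out, noise = NULL) {
  if (is.null(noise)) {
    noise <- matrix(stats::rnorm(length(out$mean)), nrow(out$mean))
  }
  out$mean + exp(0.5 * out$log_variance) * noise
}

#' Sample the latent prior N(0, I)
#'
#' @param n Number of samples.
#' @param latent_dim Latent dimension K.
#' @param seed Optional integer; when given, draws are taken from a local
#'   RNG stream without disturbing the global one.
#' @return `n x K` matrix of i.i.d. standard normal draws.
#' @export
sample_prior <- function(n, latent_dim, seed = NULL) {
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (!is.null(seed)) {
    return(.with_local_seed(seed, matrix(stats::rnorm(n * latent_dim), n)))
  }
  matrix(stats::rnorm(n * latent_dim), n, latent_dim)
}

.with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- decoder ---------------------------------------------------------------

#' Build a ZINB decoder
#'
#' MLP trunk from the latent space followed by three width-G heads giving
#' the ZINB parameters: `mu` and `theta` through exponential links clamped
#' to `[1e-8, 1e8]`, `pi` through a sigmoid. Outputs are valid ZINB
#' parameters for any finite latent code.
#'
#' @param latent_dim Latent dimension K.
#' @param d_out Output width (number of genes G).
#' @param spec A [network_spec()].
#' @return An object of class `avae_decoder`.
#' @export
make_decoder <- function(latent_dim, d_out, spec) {
  trunk <- .mlp_new(latent_dim, spec)
  h <- utils::tail(spec$layer_sizes, 1)
  structure(list(trunk = trunk, head_mu = .linear_new(h, d_out),
                 head_theta = .linear_new(h, d_out),
                 head_pi = .linear_new(h, d_out),
                 latent_dim = latent_dim, d_out = d_out, spec = spec),
            class = "avae_decoder")
}

.EXP_LO <- log(1e-8)
.EXP_HI <- log(1e8)

#' Decode latent codes to ZINB parameters
#'
#' @param decoder A [make_decoder()] object.
#' @param z `n x K` matrix of latent codes (finite).
#' @param train Logical; enable dropout.
#' @return List with `mu`, `theta`, `pi` (`n x G` each), satisfying
#'   `mu > 0`, `theta > 0`, `0 < pi < 1`.
#' @export
decode <- function(decoder, z, train = FALSE) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("latent codes must be finite", call. = FALSE)
  if (ncol(z) != decoder$latent_dim) {
    stop(sprintf("latent width %d does not match decoder width %d",
                 ncol(z), decoder$latent_dim), call. = FALSE)
  }
  full <- .decode_full(decoder, z, train = train)
  full[c("mu", "theta", "pi")]
}

.decode_full <- function(decoder, z, train = FALSE) {
  fw <- .mlp_forward(decoder$trunk, z, train = train)
  a_mu <- .linear_forward(decoder$head_mu, fw$H)
  a_th <- .linear_forward(decoder$head_theta, fw$H)
  a_pi <- .linear_forward(decoder$head_pi, fw$H)
  list(fw = fw, a_mu = a_mu, a_th = a_th, a_pi = a_pi,
       mu = exp(pmin(pmax(a_mu, .EXP_LO), .EXP_HI)),
       theta = exp(pmin(pmax(a_th, .EXP_LO), .EXP_HI)),
       pi = pmin(pmax(stats::plogis(a_pi), 1e-8), 1 - 1e-8))
}

# dmu/dtheta/dpi are gradients wrt the link outputs
.decoder_backward <- function(decoder, full, dmu, dtheta, dpi) {
  da_mu <- dmu * full$mu * (full$a_mu > .EXP_LO & full$a_mu < .EXP_HI)
  da_th <- dtheta * full$theta * (full$a_th > .EXP_LO & full$a_th < .EXP_HI)
  da_pi <- dpi * full$pi * (1 - full$pi)
  g1 <- .linear_backward(decoder$head_mu, full$fw$H, da_mu)
  g2 <- .linear_backward(decoder$head_theta, full$fw$H, da_th)
  g3 <- .linear_backward(decoder$head_pi, full$fw$H, da_pi)
  gt <- .mlp_backward(decoder$trunk, full$fw, g1$dH + g2$dH + g3$dH)
  list(trunk = gt, head_mu = g1, head_theta = g2, head_pi = g3)
}

# ---- discriminators --------------------------------------------------------

#' Build a discriminator / critic network
#'
#' MLP trunk plus a scalar head: sigmoid head in the probability domain
#' (standard GAN and Bhattacharyya objectives), linear head in the unbounded
#' domain (Wasserstein critics).
#'
#' @param d_in Input width (K for the latent discriminator D1, G for the
#'   data-space discriminator D2).
#' @param spec A [network_spec()].
#' @param domain `"probability"` or `"unbounded"`.
#' @return An object of class `avae_discriminator`.
#' @export
make_discriminator <- function(d_in, spec, domain = c("probability", "unbounded")) {
  domain <- match.arg(domain)
  trunk <- .mlp_new(d_in, spec)
  h <- utils::tail(spec$layer_sizes, 1)
  # small output-head init keeps early scores near the decision boundary,
  # which avoids sigmoid saturation before the critic has learned anything
  structure(list(trunk = trunk, head = .linear_new(h, 1, sd = 0.01), d_in = d_in,
                 domain = domain, spec = spec),
            class = "avae_discriminator")
}

#' Score samples with a discriminator
#'
#' @param disc A [make_discriminator()] object.
#' @param x `n x d` matrix of samples (latent codes for D1, expression
#'   vectors for D2).
#' @param train Logical; enable dropout.
#' @return Numeric vector of `n` scores; in `(0, 1)` for the probability
#'   domain, unrestricted for the unbounded domain.
#' @export
discriminate <- function(disc, x, train = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != disc$d_in) {
    stop(sprintf("input width %d does not match discriminator width %d",
                 ncol(x), disc$d_in), call. = FALSE)
  }
  full <- .discriminate_full(disc, x, train = train)
  full$score
}

#' @rdname discriminate
#' @export
discriminate_latent <- function(disc, x, train = FALSE) discriminate(disc, x, train)

#' @rdname discriminate
#' @export
discriminate_data <- function(disc, x, train = FALSE) discriminate(disc, x, train)

.discriminate_full <- function(disc, x, train = FALSE) {
  fw <- .mlp_forward(disc$trunk, x, train = train)
  a <- as.numeric(.linear_forward(disc$head, fw$H))
  score <- if (disc$domain == "probability") stats::plogis(a) else a
  list(fw = fw, a = a, score = score)
}

# dscore: gradient wrt the (post-link) scores, length n
.discriminator_backward <- function(disc, full, dscore) {
  da <- if (disc$domain == "probability") {
    dscore * full$score * (1 - full$score)
  } else dscore
  gh <- .linear_backward(disc$head, full$fw$H, matrix(da, ncol = 1))
  gt <- .mlp_backward(disc$trunk, full$fw, gh$dH)
  list(trunk = gt, head = gh, dX = gt$dX)
}

# gradient of the score wrt the input, per sample (eval mode, no dropout)
.disc_input_grad <- function(disc, x) {
  full <- .discriminate_full(disc, as.matrix(x), train = FALSE)
  .discriminator_backward(disc, full, rep(1, nrow(x)))$dX
}

# Double backprop for the WGAN-GP penalty: with LeakyReLU the activation
# second derivative vanishes a.e., so the input-gradient map is the
# "transpose network" with frozen slope factors and the parameter gradients
# of the penalty follow from backpropagating through that map. Dropout is
# disabled on interpolates. Returns the penalty value and parameter grads.
.gp_penalty_and_grads <- function(disc, xhat, weight) {
  if (disc$domain != "unbounded") {
    stop("gradient penalty applies to unbounded-domain critics", call. = FALSE)
  }
  n <- nrow(xhat)
  L <- length(disc$trunk$W)
  fw <- .mlp_forward(disc$trunk, xhat, train = FALSE)
  slopes <- lapply(seq_len(L), function(k) {
    ifelse(fw$A[[k]] > 0, 1, disc$trunk$slope)
  })
  # backward chain computing g = d score / d x per sample
  delta <- vector("list", L + 1) # delta[[k+1]] = gradient at hidden layer k
  delta[[L + 1]] <- matrix(rep(as.numeric(disc$head$W), each = n), n)
  v <- vector("list", L)
  for (k in rev(seq_len(L))) {
    v[[k]] <- delta[[k + 1]] * slopes[[k]]
    delta[[k]] <- tcrossprod(v[[k]], disc$trunk$W[[k]])
  }
  g <- delta[[1]]
  norms <- sqrt(rowSums(g^2) + 1e-12)
  penalty <- weight * mean((norms - 1)^2)
  # u = d penalty / d g
  u <- (2 * weight / n) * (norms - 1) / norms * g
  # backprop through the transpose chain
  dW <- vector("list", L)
  db <- lapply(seq_len(L), function(k) numeric(length(disc$trunk$b[[k]])))
  s <- u
  for (k in seq_len(L)) {
    dW[[k]] <- crossprod(s, v[[k]]) # (h_{k-1} x n) %*% (n x h_k)
    s <- (s %*% disc$trunk$W[[k]]) * slopes[[k]]
  }
  dhead_W <- matrix(colSums(s), ncol = 1)
  list(penalty = penalty,
       grads = list(trunk = list(dW = dW, db = db),
                    head = list(dW = dhead_W, db = 0)))
}
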