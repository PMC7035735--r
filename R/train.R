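#' Training configuration
#'
#' All knobs of one AVAE / AVAE-DM training run. Defaults follow the
#' method's protocol: batch size 128, two generator updates per
#' discriminator update, Bhattacharyya objective, N(0, I) prior, Adam.
#'
#' @param latent_dim Latent dimension K (2, 10, and 20 are the standard
#'   choices; any positive integer is accepted).
#' @param objective One of `"bhattacharyya"` (the AVAE-DM default),
#'   `"standard"`, `"wasserstein"`, `"wasserstein_gp"`.
#' @param encoder_spec,decoder_spec,d1_spec,d2_spec [network_spec()]s for
#'   the four networks.
#' @param batch_size Minibatch size (at least 2; default 128).
#' @param learning_rate Adam learning rate for all networks.
#' @param epochs Maximum number of epochs (default 300).
#' @param gen_updates_per_disc Generator updates per discriminator update
#'   (default 2).
#' @param dual_matching `TRUE` for AVAE-DM (data-space discriminator D2),
#'   `FALSE` for the plain AVAE ablation.
#' @param seed Integer seed controlling every source of randomness in the
#'   run (initialization, shuffling, noise, dropout).
#' @param loss_weights Named numeric vector with entries `reconstruction`,
#'   `latent_adv`, `data_adv` (all default 1).
#' @param gp_weight Gradient-penalty coefficient for the
#'   `"wasserstein_gp"` objective (default 10).
#' @param early_stopping_patience Stop when the epoch reconstruction loss
#'   has not improved for this many epochs (default 30); `Inf` disables.
#' @param verbose Print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(latent_dim = 2,
                         objective = c("bhattacharyya", "standard",
                                       "wasserstein", "wasserstein_gp"),
                         encoder_spec = network_spec(c(128, 128)),
                         decoder_spec = network_spec(c(128, 128)),
                         d1_spec = network_spec(c(32, 32)),
                         d2_spec = network_spec(c(32, 32)),
                         batch_size = 128,
                         learning_rate = 1e-3,
                         epochs = 300,
                         gen_updates_per_disc = 2,
                         dual_matching = TRUE,
                         seed = 0,
                         loss_weights = c(reconstruction = 1, latent_adv = 1,
                                          data_adv = 1),
                         gp_weight = 10,
                         early_stopping_patience = 30,
                         verbose = FALSE) {
  objective <- match.arg(objective)
  if (latent_dim < 1) stop("'latent_dim' must be positive", call. = FALSE)
  if (batch_size < 2) {
    stop("'batch_size' must be at least 2 (per-batch score variance is needed)",
         call. = FALSE)
  }
  if (learning_rate <= 0) stop("'learning_rate' must be positive", call. = FALSE)
  if (epochs < 1) stop("'epochs' must be positive", call. = FALSE)
  if (gen_updates_per_disc < 1) {
    stop("'gen_updates_per_disc' must be positive", call. = FALSE)
  }
  req <- c("reconstruction", "latent_adv", "data_adv")
  if (!all(req %in% names(loss_weights)) || any(loss_weights <= 0)) {
    stop("'loss_weights' must name positive reconstruction/latent_adv/data_adv weights",
         call. = FALSE)
  }
  for (s in list(encoder_spec, decoder_spec, d1_spec, d2_spec)) {
    stopifnot(inherits(s, "network_spec"))
  }
  structure(list(latent_dim = as.integer(latent_dim), objective = objective,
                 encoder_spec = encoder_spec, decoder_spec = decoder_spec,
                 d1_spec = d1_spec, d2_spec = d2_spec,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 gen_updates_per_disc = as.integer(gen_updates_per_disc),
                 dual_matching = isTRUE(dual_matching), seed = as.integer(seed),
                 loss_weights = loss_weights[req], gp_weight = gp_weight,
                 early_stopping_patience = early_stopping_patience,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# parameter-tree extraction / injection -------------------------------------

.enc_params <- function(e) list(trunk = list(W = e$trunk$W, b = e$trunk$b),
                                head_mean = e$head_mean, head_logvar = e$head_logvar)
.enc_inject <- function(e, p) {
  e$trunk$W <- p$trunk$W; e$trunk$b <- p$trunk$b
  e$head_mean <- p$head_mean; e$head_logvar <- p$head_logvar
  e
}
.enc_gtree <- function(g) list(
  trunk = list(W = g$trunk$dW, b = g$trunk$db),
  head_mean = list(W = g$head_mean$dW, b = g$head_mean$db),
  head_logvar = list(W = g$head_logvar$dW, b = g$head_logvar$db))

.dec_params <- function(d) list(trunk = list(W = d$trunk$W, b = d$trunk$b),
                                head_mu = d$head_mu, head_theta = d$head_theta,
                                head_pi = d$head_pi)
.dec_inject <- function(d, p) {
  d$trunk$W <- p$trunk$W; d$trunk$b <- p$trunk$b
  d$head_mu <- p$head_mu; d$head_theta <- p$head_theta; d$head_pi <- p$head_pi
  d
}
.dec_gtree <- function(g) list(
  trunk = list(W = g$trunk$dW, b = g$trunk$db),
  head_mu = list(W = g$head_mu$dW, b = g$head_mu$db),
  head_theta = list(W = g$head_theta$dW, b = g$head_theta$db),
  head_pi = list(W = g$head_pi$dW, b = g$head_pi$db))

.disc_params <- function(d) list(trunk = list(W = d$trunk$W, b = d$trunk$b),
                                 head = d$head)
.disc_inject <- function(d, p) {
  d$trunk$W <- p$trunk$W; d$trunk$b <- p$trunk$b; d$head <- p$head
  d
}
.disc_gtree <- function(g) list(trunk = list(W = g$trunk$dW, b = g$trunk$db),
                                head = list(W = g$head$dW, b = g$head$db))

.clamp_scores <- function(s, domain) {
  if (domain == "probability") pmin(pmax(s, 1e-7), 1 - 1e-7) else s
}

.mk_scores <- function(real, fake, domain) {
  structure(list(real_scores = .clamp_scores(real, domain),
                 fake_scores = .clamp_scores(fake, domain),
                 domain = domain), class = "score_batch")
}

.check_finite <- function(value, step) {
  if (any(!is.finite(value))) {
    stop(sprintf("non-finite loss encountered during the %s step; try a lower learning rate",
                 step), call. = FALSE)
  }
  invisible(value)
}

#' Train an AVAE / AVAE-DM model
#'
#' Runs the adversarial training loop. Per minibatch: (a) an autoencoder
#' step minimizing the ZINB reconstruction NLL of the raw counts given
#' `decode(reparameterize(encode(x)))`; (b) a latent discriminator (D1)
#' step on prior samples vs posterior samples; (c) `gen_updates_per_disc`
#' encoder-as-generator steps against D1; and, when `dual_matching`, (d) a
#' data-space discriminator (D2) step on real vs reconstructed expression
#' and (e) generator steps against D2 at the same ratio. All four networks
#' are optimized with Adam at `config$learning_rate`; every source of
#' randomness derives from `config$seed`, so identical inputs give
#' bit-identical results.
#'
#' The reconstruction fed to D2 is the expected count `mu * (1 - pi)`,
#' compared with the real data on the `log2(1 + .)` scale.
#'
#' @param x A [processed_matrix()][log_transform()] (or plain matrix of
#'   `log2(1 + C)` values) for the training cells.
#' @param counts Optional matching [count_matrix()] of raw counts for the
#'   same cells and the same gene panel; when `NULL`, counts are recovered
#'   from `x` as `2^x - 1` (exact for log2(1+C) input).
#' @param config A [train_config()].
#' @return An object of class `avae_model` with the trained networks, the
#'   config, the training gene panel, and `history`: a data frame with one
#'   row per completed epoch (reconstruction loss, D1/D2 losses, generator
#'   losses).
#' @export
train_model <- function(x, counts = NULL, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  gene_ids <- NULL
  if (inherits(x, "processed_matrix")) {
    gene_ids <- x$source_gene_ids
    xm <- x$values
  } else {
    xm <- as.matrix(x)
  }
  if (is.null(counts)) {
    raw <- round(2^xm - 1)
  } else {
    stopifnot(inherits(counts, "count_matrix"))
    raw <- counts$values
    if (!all(dim(raw) == dim(xm))) {
      stop("'counts' must match 'x' in dimension (same cells, same gene panel)",
           call. = FALSE)
    }
  }
  M <- nrow(xm); G <- ncol(xm); K <- config$latent_dim
  if (M < 1) stop("'x' must contain at least one cell", call. = FALSE)
  if (config$batch_size > M) {
    stop(sprintf("batch_size (%d) exceeds the number of cells (%d)",
                 config$batch_size, M), call. = FALSE)
  }
  domain <- .objective_domain(config$objective)
  w <- config$loss_weights

  set.seed(config$seed)
  enc <- make_encoder(G, K, config$encoder_spec)
  dec <- make_decoder(K, G, config$decoder_spec)
  d1 <- make_discriminator(K, config$d1_spec, domain)
  d2 <- if (config$dual_matching) {
    make_discriminator(G, config$d2_spec, domain)
  } else NULL

  opt_enc <- .adam_init(.enc_params(enc))
  opt_dec <- .adam_init(.dec_params(dec))
  opt_d1 <- .adam_init(.disc_params(d1))
  opt_d2 <- if (config$dual_matching) .adam_init(.disc_params(d2)) else NULL
  lr <- config$learning_rate

  hist <- vector("list", config$epochs)
  best_recon <- Inf
  best_epoch <- 0L

  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(M)
    starts <- seq(1, M, by = config$batch_size)
    ep <- c(recon = 0, d1_loss = 0, gen1_loss = 0, d2_loss = 0, gen2_loss = 0)
    nb <- 0L
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, M)]
      if (length(idx) < 2) next # per-batch variance undefined for singletons
      xb <- xm[idx, , drop = FALSE]
      rb <- raw[idx, , drop = FALSE]
      b <- length(idx)

      # (a) autoencoder step -------------------------------------------------
      ef <- .encode_full(enc, xb, train = TRUE)
      epsil <- matrix(stats::rnorm(b * K), b, K)
      sd_z <- exp(0.5 * ef$log_variance)
      z <- ef$mean + sd_z * epsil
      df <- .decode_full(dec, z, train = TRUE)
      pic <- pmin(pmax(df$pi, 1e-8), 1 - 1e-8)
      recon <- zinb_reconstruction_loss(rb, df$mu, df$theta, pic)
      .check_finite(recon, "reconstruction")
      gr <- .zinb_nll_grads(rb, df$mu, df$theta, pic)
      dgrad <- .decoder_backward(dec, df, w["reconstruction"] * gr$dmu,
                                 w["reconstruction"] * gr$dtheta,
                                 w["reconstruction"] * gr$dpi)
      dz <- dgrad$trunk$dX
      egrad <- .encoder_backward(enc, ef, dz, dz * epsil * 0.5 * sd_z)
      up <- .adam_step(.enc_params(enc), .enc_gtree(egrad), opt_enc, lr)
      enc <- .enc_inject(enc, up$params); opt_enc <- up$state
      up <- .adam_step(.dec_params(dec), .dec_gtree(dgrad), opt_dec, lr)
      dec <- .dec_inject(dec, up$params); opt_dec <- up$state

      # (b) latent discriminator step ----------------------------------------
      z_fake <- reparameterize(encode(enc, xb), matrix(stats::rnorm(b * K), b, K))
      z_real <- matrix(stats::rnorm(b * K), b, K)
      fullD <- .discriminate_full(d1, rbind(z_real, z_fake), train = TRUE)
      sc <- .mk_scores(fullD$score[seq_len(b)], fullD$score[b + seq_len(b)], domain)
      dl <- adversarial_loss(sc, config$objective)
      .check_finite(dl$discriminator_loss, "latent discriminator")
      gsc <- .adversarial_grads(sc, config$objective)
      dgr <- .discriminator_backward(d1, fullD, c(gsc$d_disc_real, gsc$d_disc_fake))
      gtree <- .disc_gtree(dgr)
      d1_loss <- dl$discriminator_loss
      if (config$objective == "wasserstein_gp") {
        epsu <- stats::runif(b)
        xhat <- epsu * z_real + (1 - epsu) * z_fake
        gp <- .gp_penalty_and_grads(d1, xhat, config$gp_weight)
        gtree <- .tree_add(gtree, gp$grads)
        d1_loss <- d1_loss + gp$penalty
      }
      up <- .adam_step(.disc_params(d1), gtree, opt_d1, lr)
      d1 <- .disc_inject(d1, up$params); opt_d1 <- up$state

      # (c) encoder-as-generator steps against D1 ----------------------------
      gen1 <- 0
      for (r in seq_len(config$gen_updates_per_disc)) {
        ef <- .encode_full(enc, xb, train = TRUE)
        epsil <- matrix(stats::rnorm(b * K), b, K)
        sd_z <- exp(0.5 * ef$log_variance)
        zf <- ef$mean + sd_z * epsil
        z_real <- matrix(stats::rnorm(b * K), b, K)
        sreal <- discriminate(d1, z_real, train = TRUE)
        fullF <- .discriminate_full(d1, zf, train = TRUE)
        sc <- .mk_scores(sreal, fullF$score, domain)
        gl <- adversarial_loss(sc, config$objective)$generator_loss
        .check_finite(gl, "latent generator")
        gsc <- .adversarial_grads(sc, config$objective)
        dzf <- .discriminator_backward(d1, fullF,
                                       w["latent_adv"] * gsc$d_gen_fake)$dX
        egrad <- .encoder_backward(enc, ef, dzf, dzf * epsil * 0.5 * sd_z)
        up <- .adam_step(.enc_params(enc), .enc_gtree(egrad), opt_enc, lr)
        enc <- .enc_inject(enc, up$params); opt_enc <- up$state
        gen1 <- gen1 + gl / config$gen_updates_per_disc
      }

      d2_loss <- NA_real_; gen2 <- NA_real_
      if (config$dual_matching) {
        # (d) data-space discriminator step ----------------------------------
        zz <- reparameterize(encode(enc, xb), matrix(stats::rnorm(b * K), b, K))
        pr <- decode(dec, zz)
        xhat <- log2(1 + pr$mu * (1 - pr$pi))
        fullD <- .discriminate_full(d2, rbind(xb, xhat), train = TRUE)
        sc <- .mk_scores(fullD$score[seq_len(b)], fullD$score[b + seq_len(b)], domain)
        dl2 <- adversarial_loss(sc, config$objective)
        .check_finite(dl2$discriminator_loss, "data discriminator")
        gsc <- .adversarial_grads(sc, config$objective)
        dgr <- .discriminator_backward(d2, fullD, c(gsc$d_disc_real, gsc$d_disc_fake))
        gtree <- .disc_gtree(dgr)
        d2_loss <- dl2$discriminator_loss
        if (config$objective == "wasserstein_gp") {
          epsu <- stats::runif(b)
          xhat2 <- epsu * xb + (1 - epsu) * xhat
          gp <- .gp_penalty_and_grads(d2, xhat2, config$gp_weight)
          gtree <- .tree_add(gtree, gp$grads)
          d2_loss <- d2_loss + gp$penalty
        }
        up <- .adam_step(.disc_params(d2), gtree, opt_d2, lr)
        d2 <- .disc_inject(d2, up$params); opt_d2 <- up$state

        # (e) generator steps against D2 -------------------------------------
        gen2 <- 0
        ln2 <- log(2)
        for (r in seq_len(config$gen_updates_per_disc)) {
          ef <- .encode_full(enc, xb, train = TRUE)
          epsil <- matrix(stats::rnorm(b * K), b, K)
          sd_z <- exp(0.5 * ef$log_variance)
          zf <- ef$mean + sd_z * epsil
          dfull <- .decode_full(dec, zf, train = TRUE)
          expct <- dfull$mu * (1 - dfull$pi)
          xhat <- log2(1 + expct)
          sreal <- discriminate(d2, xb, train = TRUE)
          fullF <- .discriminate_full(d2, xhat, train = TRUE)
          sc <- .mk_scores(sreal, fullF$score, domain)
          gl2 <- adversarial_loss(sc, config$objective)$generator_loss
          .check_finite(gl2, "data generator")
          gsc <- .adversarial_grads(sc, config$objective)
          dxhat <- .discriminator_backward(d2, fullF,
                                           w["data_adv"] * gsc$d_gen_fake)$dX
          base <- dxhat / ((1 + expct) * ln2)
          dgrad <- .decoder_backward(dec, dfull, base * (1 - dfull$pi),
                                     matrix(0, b, G), -base * dfull$mu)
          dzf <- dgrad$trunk$dX
          egrad <- .encoder_backward(enc, ef, dzf, dzf * epsil * 0.5 * sd_z)
          up <- .adam_step(.enc_params(enc), .enc_gtree(egrad), opt_enc, lr)
          enc <- .enc_inject(enc, up$params); opt_enc <- up$state
          up <- .adam_step(.dec_params(dec), .dec_gtree(dgrad), opt_dec, lr)
          dec <- .dec_inject(dec, up$params); opt_dec <- up$state
          gen2 <- gen2 + gl2 / config$gen_updates_per_disc
        }
      }

      ep <- ep + c(recon, d1_loss, gen1,
                   if (is.na(d2_loss)) 0 else d2_loss,
                   if (is.na(gen2)) 0 else gen2)
      nb <- nb + 1L
    }
    ep <- ep / nb
    if (!config$dual_matching) ep[c("d2_loss", "gen2_loss")] <- NA_real_
    hist[[epoch]] <- ep
    if (config$verbose) {
      message(sprintf("epoch %3d  recon %.3f  d1 %.4f  gen1 %.4f  d2 %s  gen2 %s",
                      epoch, ep["recon"], ep["d1_loss"], ep["gen1_loss"],
                      format(ep["d2_loss"], digits = 3),
                      format(ep["gen2_loss"], digits = 3)))
    }
    if (ep["recon"] < best_recon - 1e-6) {
      best_recon <- ep["recon"]
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= config$early_stopping_patience) break
  }

  history <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  names(history) <- c("reconstruction", "d1_loss", "gen1_loss", "d2_loss",
                      "gen2_loss")
  history$epoch <- seq_len(nrow(history))
  structure(list(encoder = enc, decoder = dec, d1 = d1, d2 = d2,
                 config = config, gene_ids = gene_ids, n_genes = G,
                 history = history[, c("epoch", "reconstruction", "d1_loss",
                                       "gen1_loss", "d2_loss", "gen2_loss")]),
            class = "avae_model")
}

#' @export
print.avae_model <- function(x, ...) {
  cat(sprintf(
    "avae_model: K = %d, objective = %s, dual_matching = %s, %d epochs trained\n",
    x$config$latent_dim, x$config$objective, x$config$dual_matching,
    nrow(x$history)))
  invisible(x)
}

#' Project cells into the latent space
#'
#' Returns the posterior mean of q(z|x) per cell — the deterministic
#' embedding used for clustering, evaluation and visualization (no
#' sampling, dropout off).
#'
#' @param model A trained [train_model()] result.
#' @param x A `processed_matrix` or plain matrix over the training gene
#'   panel.
#' @return `M x K` matrix of latent coordinates.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "avae_model"))
  if (inherits(x, "processed_matrix")) {
    if (!is.null(model$gene_ids) &&
        !identical(x$source_gene_ids, model$gene_ids)) {
      missing <- setdiff(model$gene_ids, x$source_gene_ids)
      stop(sprintf("gene panel does not match the training panel (%d missing: %s%s)",
                   length(missing),
                   paste(utils::head(missing, 5), collapse = ", "),
                   if (length(missing) > 5) ", ..." else ""), call. = FALSE)
    }
    x <- x$values
  }
  x <- as.matrix(x)
  if (ncol(x) != model$n_genes) {
    stop(sprintf("input has %d genes; the model was trained on %d",
                 ncol(x), model$n_genes), call. = FALSE)
  }
  encode(model$encoder, x, train = FALSE)$mean
}
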