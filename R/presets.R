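# Published hyperparameter presets for the five reference scRNA-seq
# datasets, one row per (dataset, K): batch size 128 throughout, generator
# (encoder; the decoder mirrors it) and discriminator layer widths, and the
# Adam learning rate.
.PRESETS <- list(
  "rosenberg156k.2" = list(g = c(1024, 512, 512, 256), d = c(32, 16, 16, 8), lr = 7e-5),
  "zheng73k.2" = list(g = c(512, 512, 512), d = c(32, 32, 32), lr = 6e-5),
  "zheng68k.2" = list(g = c(256, 256, 256, 256), d = c(32, 32, 16, 16), lr = 1e-4),
  "macosko44k.2" = list(g = c(256, 128, 64), d = c(64, 64, 64), lr = 1e-4),
  "zeisel3k.2" = list(g = c(512, 512, 512, 512), d = c(32, 32, 32, 32), lr = 8e-4),
  "rosenberg156k.10" = list(g = c(512, 256, 128, 64), d = c(256, 128, 64, 32), lr = 6e-5),
  "zheng73k.10" = list(g = c(1024, 512, 512, 256), d = c(32, 32, 32, 32), lr = 2e-5),
  "zheng68k.10" = list(g = c(256, 256, 256, 256), d = c(32, 32, 16, 16), lr = 7e-5),
  "macosko44k.10" = list(g = c(512, 256, 256, 128), d = c(256, 128, 128, 64), lr = 7e-5),
  "zeisel3k.10" = list(g = 512, d = 512, lr = 7e-4),
  "rosenberg156k.20" = list(g = c(1024, 1024, 1024, 1024), d = c(64, 64, 64, 64), lr = 6e-5),
  "zheng73k.20" = list(g = c(1024, 512, 512, 256), d = c(64, 32, 32, 16), lr = 1e-5),
  "zheng68k.20" = list(g = 256, d = 256, lr = 2e-5),
  "macosko44k.20" = list(g = 256, d = 256, lr = 7e-5),
  "zeisel3k.20" = list(g = 512, d = 512, lr = 7e-4)
)

#' Hyperparameter presets for the reference datasets
#'
#' Returns the tuned [train_config()] for one of the five reference
#' scRNA-seq datasets at latent dimension 2, 10, or 20: batch size 128, the
#' published generator and discriminator layer widths, and the published
#' learning rate. The decoder mirrors the encoder's layer widths in reverse;
#' both discriminators share the discriminator spec.
#'
#' @param dataset_tag One of `"zeisel3k"`, `"macosko44k"`, `"zheng68k"`,
#'   `"zheng73k"`, `"rosenberg156k"`.
#' @param K Latent dimension: 2, 10, or 20.
#' @param ... Further arguments passed to [train_config()] (e.g. `epochs`,
#'   `seed`).
#' @return A [train_config()].
#' @examples
#' cfg <- preset_config("zeisel3k", K = 2)
#' cfg$learning_rate # 8e-4
#' @export
preset_config <- function(dataset_tag, K, ...) {
  tags <- unique(sub("\\.\\d+$", "", names(.PRESETS)))
  if (!dataset_tag %in% tags) {
    stop(sprintf("unknown dataset tag '%s'; available: %s", dataset_tag,
                 paste(tags, collapse = ", ")), call. = FALSE)
  }
  key <- paste0(dataset_tag, ".", K)
  p <- .PRESETS[[key]]
  if (is.null(p)) {
    stop(sprintf("no preset for dataset '%s' at K = %s (K must be 2, 10, or 20)",
                 dataset_tag, K), call. = FALSE)
  }
  train_config(latent_dim = K,
               encoder_spec = network_spec(p$g),
               decoder_spec = network_spec(rev(p$g)),
               d1_spec = network_spec(p$d),
               d2_spec = network_spec(p$d),
               batch_size = 128,
               learning_rate = p$lr,
               ...)
}

#' List all hyperparameter presets
#'
#' @return Data frame with one row per (dataset, K) preset: layer widths as
#'   slash-separated strings, batch size, learning rate.
#' @export
list_presets <- function() {
  rows <- lapply(names(.PRESETS), function(k) {
    p <- .PRESETS[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(dataset = parts[1], K = as.integer(parts[2]), batch_size = 128L,
               g_layers = paste(p$g, collapse = "/"),
               d_layers = paste(p$d, collapse = "/"),
               learning_rate = p$lr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
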