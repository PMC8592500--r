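# Shared fixtures, generated in code and memoised across test files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# Quiet desk-scale dataset: 8-channel, 256 Hz, 8 s segments -> 64x64 images.
desk_images <- function(n_per_class = 25, seed = 7) {
  memo(sprintf("desk_%d_%d", n_per_class, seed), {
    cfg <- sim_preset("desk", seed = seed)
    segs <- simulate_dataset(cfg, n_per_class)
    pc <- preprocess_config(window_s = 1, out_size = 64, line_freq = 60)
    preprocess_dataset(segs, pc, quiet = TRUE)
  })
}

# Fast synthetic spectrogram-like images: a bright horizontal band whose row
# position depends on the class, plus noise. Useful where only a separable
# image dataset is needed and the signal-processing path is not under test.
stripe_images <- function(n_per_class, size = 16, seed = 1, noise = 0.2,
                          source = "real") {
  withr_seed <- function(expr) spectrogan:::with_seed(seed, expr)
  withr_seed({
    mk <- function(label, i, t0) {
      row <- if (label == "preictal") round(size * 0.75) else round(size * 0.25)
      m <- matrix(stats::rnorm(size * size, 0, noise), size, size)
      m[max(1, row - 1):min(size, row + 1), ] <-
        m[max(1, row - 1):min(size, row + 1), ] + 1
      m <- pmin(pmax(m, -1), 1)
      spectrogram_image(array(m, c(size, size, 3)), label = label,
                        source = source, t_start = t0)
    }
    out <- list()
    for (i in seq_len(n_per_class)) {
      out[[2 * i - 1]] <- mk("interictal", i, (2 * i - 2) * 8)
      out[[2 * i]] <- mk("preictal", i, (2 * i - 1) * 8)
    }
    out
  })
}

# A tiny GAN configuration producing 16x16 images, for smoke tests.
tiny_gan <- function(seed = 1) {
  build_gan(generator_config(latent_dim = 16, dense_out = 4 * 4 * 8,
                             reshape_to = c(4, 4, 8), n_deconv = 2,
                             deconv_filters = c(8, 8)),
            discriminator_config(conv_filters = c(8, 8)),
            out_size = 16, class_label = "preictal", seed = seed)
}

label_of <- function(images) vapply(images, function(im) im$label, "")
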