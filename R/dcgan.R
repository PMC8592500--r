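# ---- deep convolutional GAN ------------------------------------------------

#' Generator configuration
#'
#' The default preset maps a 100-dimensional standard-Gaussian latent vector
#' through a dense layer of width 4096, reshapes to `4 x 4 x 256`, and
#' applies `n_deconv` stride-2 transposed convolutions (5x5 kernels, same
#' padding) with the given filter counts, followed by a stride-1 convolution
#' to `output_channels` with a tanh head. The side therefore grows as
#' `4 * 2^n_deconv` and must equal the requested image size.
#'
#' @param latent_dim latent dimension (default 100).
#' @param dense_out width of the first dense layer; must equal
#'   `prod(reshape_to)`.
#' @param reshape_to spatial seed shape `c(h, w, c)` after the dense layer.
#' @param n_deconv number of stride-2 transposed convolution layers.
#' @param deconv_filters filter counts, one per deconv layer.
#' @param kernel kernel side (default 5).
#' @param output_channels image channels (default 3).
#' @param batchnorm apply batch normalization after every hidden layer.
#' @return A `generator_config` object.
#' @export
generator_config <- function(latent_dim = 100, dense_out = 4096,
                             reshape_to = c(4, 4, 256), n_deconv = 6,
                             deconv_filters = c(256, 128, 128, 128, 128, 128),
                             kernel = 5, output_channels = 3,
                             batchnorm = TRUE) {
  stopifnot(length(deconv_filters) == n_deconv,
            dense_out == prod(reshape_to))
  structure(list(latent_dim = as.integer(latent_dim),
                 dense_out = as.integer(dense_out),
                 reshape_to = as.integer(reshape_to),
                 n_deconv = as.integer(n_deconv),
                 deconv_filters = as.integer(deconv_filters),
                 kernel = as.integer(kernel),
                 output_channels = as.integer(output_channels),
                 batchnorm = isTRUE(batchnorm)),
            class = "generator_config")
}

#' Discriminator configuration
#'
#' Stride-2 "same"-padded convolutions (5x5 kernels) with leaky-ReLU
#' activations, flattened into a single sigmoid real-vs-generated score.
#' The default preset uses 4 layers with 256, 128, 64 and 32 filters.
#'
#' @param conv_filters filter counts, one per convolution layer.
#' @param kernel kernel side (default 5).
#' @param lrelu_alpha leaky-ReLU slope for negative inputs.
#' @return A `discriminator_config` object.
#' @export
discriminator_config <- function(conv_filters = c(256, 128, 64, 32),
                                 kernel = 5, lrelu_alpha = 0.2) {
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), lrelu_alpha = lrelu_alpha),
            class = "discriminator_config")
}

# Quarter-scale configurations for 64 x 64 experimentation.
#' Desk-scale GAN configurations
#'
#' Quarter-scale generator (`4 * 2^4 = 64` pixel side, filters divided by 4)
#' and discriminator for fast CPU experiments on 64x64 images.
#' @name gan_desk
#' @return A `generator_config` / `discriminator_config`.
#' @export
generator_config_desk <- function() {
  generator_config(dense_out = 1024, reshape_to = c(4, 4, 64), n_deconv = 4,
                   deconv_filters = c(64, 32, 32, 32))
}

#' @rdname gan_desk
#' @export
discriminator_config_desk <- function() {
  discriminator_config(conv_filters = c(64, 32, 16, 8))
}

#' Build the generator network
#'
#' @param cfg a [generator_config()].
#' @param out_size image side S; must equal
#'   `reshape_to[1] * 2^n_deconv`.
#' @return A `sg_generator`: the network plus its configuration. Call it on
#'   latent vectors with [generator_forward()] or draw samples via
#'   [sample_gan()].
#' @export
build_generator <- function(cfg, out_size) {
  side <- cfg$reshape_to[1] * 2^cfg$n_deconv
  if (side != out_size)
    stop(sprintf(paste0("out_size %d needs n_deconv = %d (4 * 2^n); ",
                        "config has n_deconv = %d giving side %d"),
                 out_size, round(log2(out_size / cfg$reshape_to[1])),
                 cfg$n_deconv, side))
  layers <- list(nn_dense(cfg$latent_dim, cfg$dense_out, init_sd = 0.02))
  if (cfg$batchnorm) layers <- c(layers, list(nn_bn(cfg$dense_out)))
  layers <- c(layers, list(nn_act("relu"), nn_reshape(cfg$reshape_to)))
  c_prev <- cfg$reshape_to[3]
  for (i in seq_len(cfg$n_deconv)) {
    layers <- c(layers, list(nn_convt(cfg$kernel, c_prev,
                                      cfg$deconv_filters[i], init_sd = 0.02)))
    if (cfg$batchnorm) layers <- c(layers, list(nn_bn(cfg$deconv_filters[i])))
    layers <- c(layers, list(nn_act("relu")))
    c_prev <- cfg$deconv_filters[i]
  }
  layers <- c(layers, list(nn_conv(cfg$kernel, c_prev, cfg$output_channels,
                                   stride = 1, init_sd = 0.02),
                           nn_act("tanh")))
  structure(list(net = nn_network(layers), config = cfg,
                 out_size = as.integer(out_size)), class = "sg_generator")
}

#' Forward pass of a generator
#'
#' @param gen a `sg_generator` from [build_generator()].
#' @param z latent matrix, `latent_dim x batch`.
#' @param training use batch statistics in batch-norm layers.
#' @return `(S, S, 3, batch)` array of images in `[-1, 1]`.
#' @export
generator_forward <- function(gen, z, training = FALSE) {
  nn_forward(gen$net, z, training = training)$out
}

#' Build the discriminator network
#'
#' @param cfg a [discriminator_config()].
#' @param in_size input image side; must be divisible by
#'   `2^length(conv_filters)`.
#' @return A `sg_discriminator`. Score images with
#'   [discriminator_forward()], which returns probabilities in `(0, 1)`.
#' @export
build_discriminator <- function(cfg, in_size) {
  n <- length(cfg$conv_filters)
  if (in_size %% 2^n != 0)
    stop(sprintf("in_size %d is not divisible by 2^%d", in_size, n))
  layers <- list()
  c_prev <- 3L
  for (i in seq_len(n)) {
    layers <- c(layers, list(nn_conv(cfg$kernel, c_prev, cfg$conv_filters[i],
                                     stride = 2, init_sd = 0.02),
                             nn_act("lrelu", alpha = cfg$lrelu_alpha)))
    c_prev <- cfg$conv_filters[i]
  }
  side <- in_size / 2^n
  layers <- c(layers, list(nn_flatten(),
                           nn_dense(side * side * c_prev, 1, init_sd = 0.02)))
  structure(list(net = nn_network(layers), config = cfg,
                 in_size = as.integer(in_size)), class = "sg_discriminator")
}

#' Forward pass of a discriminator
#'
#' @param disc a `sg_discriminator`.
#' @param x `(S, S, 3, batch)` image array.
#' @return Vector of probabilities of being real, strictly in `(0, 1)`.
#' @export
discriminator_forward <- function(disc, x) {
  as.vector(sigmoid(nn_forward(disc$net, x)$out))
}

.clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Discriminator loss
#'
#' The mini-max value `(1/n) sum[log D(x) + log(1 - D(G(z)))]`, which the
#' discriminator update maximizes (equivalently, it minimizes the negative,
#' i.e. binary cross-entropy with targets real = 1, fake = 0).
#' Probabilities are clamped at `1e-7` before the logarithms.
#'
#' @param d_real probabilities assigned to real images.
#' @param d_fake probabilities assigned to generated images.
#' @return Scalar loss value (non-positive).
#' @export
d_loss <- function(d_real, d_fake) {
  if (!length(d_real) || !length(d_fake)) stop("empty batch")
  mean(log(.clamp_prob(d_real)) + log(1 - .clamp_prob(d_fake)))
}

#' Generator loss (non-saturating)
#'
#' `-(1/n) sum log D(G(z))`: minimized when the discriminator is fooled.
#' This is the standard non-saturating form of the generator objective;
#' the saturating alternative `(1/n) sum log(1 - D(G(z)))` has vanishing
#' gradients early in training and a form written in terms of real data
#' alone carries no generator gradient at all.
#'
#' @param d_fake probabilities assigned to generated images.
#' @return Scalar loss value (non-negative).
#' @export
g_loss <- function(d_fake) {
  if (!length(d_fake)) stop("empty batch")
  -mean(log(.clamp_prob(d_fake)))
}

#' Replay the GAN early-stopping rule over a loss history
#'
#' Training stops once the recorded discriminator loss exceeds the
#' generator loss for `k` consecutive batches; the violation streak resets
#' to zero whenever `d <= g`.
#'
#' @param d_hist,g_hist per-batch loss records.
#' @param k consecutive-violation threshold (default 15).
#' @return The 1-based batch index at which training stops, or `Inf` if the
#'   rule never fires.
#' @export
early_stop_index <- function(d_hist, g_hist, k = 15) {
  streak <- 0L
  for (i in seq_along(d_hist)) {
    streak <- if (d_hist[i] > g_hist[i]) streak + 1L else 0L
    if (streak >= k) return(i)
  }
  Inf
}

#' Assemble an untrained GAN
#'
#' @param gen_cfg a [generator_config()].
#' @param disc_cfg a [discriminator_config()].
#' @param out_size image side S.
#' @param class_label the class the GAN is trained on; stamped onto samples.
#' @param seed seed used to draw the initial weights.
#' @return A `gan_model` holding the generator, discriminator and an empty
#'   training state.
#' @export
build_gan <- function(gen_cfg = generator_config(),
                      disc_cfg = discriminator_config(),
                      out_size = 256, class_label = "preictal", seed = 1L) {
  with_seed(seed, {
    gen <- build_generator(gen_cfg, out_size)
    disc <- build_discriminator(disc_cfg, out_size)
    structure(list(generator = gen, discriminator = disc,
                   class_label = class_label,
                   train_state = list(epoch = 0L, batch = 0L,
                                      violation_streak = 0L,
                                      stopped_early = FALSE, seed = NA_integer_,
                                      history = data.frame(d_loss = numeric(0),
                                                           g_loss = numeric(0)))),
              class = "gan_model")
  })
}

#' Train a GAN on spectrogram images
#'
#' Alternating per-batch updates: one discriminator step (binary
#' cross-entropy, targets real = 1 / fake = 0) then one generator step
#' (non-saturating loss), both with Adam (`beta1 = 0.5` by default,
#' learning rate `1e-3`). After every batch the recorded monitors are the
#' discriminator's mean BCE over the real and fake half-batches and the
#' generator BCE; when the discriminator monitor exceeds the generator
#' monitor for `k = 15` consecutive batches, training stops early.
#'
#' @param gan a `gan_model` from [build_gan()].
#' @param images list of [spectrogram_image()] training images (at least
#'   one full batch).
#' @param batch_size mini-batch size (default 32).
#' @param k early-stopping consecutive-violation threshold (default 15).
#' @param lr Adam learning rate (default 1e-3).
#' @param beta1 Adam first-moment decay (default 0.5).
#' @param max_epochs maximum training epochs.
#' @param seed RNG seed controlling shuffling and latent draws.
#' @param verbose print a per-epoch loss line.
#' @return The trained `gan_model` with an updated `train_state` (full
#'   per-batch loss history, early-stop flag and streak).
#' @export
train_gan <- function(gan, images, batch_size = 32, k = 15, lr = 1e-3,
                      beta1 = 0.5, max_epochs = 10, seed = 1L,
                      verbose = FALSE) {
  stopifnot(inherits(gan, "gan_model"))
  if (length(images) < batch_size)
    stop("need at least one full batch (", batch_size, " images); got ",
         length(images))
  x_all <- image_tensor(images)
  n <- dim(x_all)[4]
  latent <- gan$generator$config$latent_dim
  st <- gan$train_state
  st$seed <- as.integer(seed)
  d_hist <- st$history$d_loss
  g_hist <- st$history$g_loss
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      n_batch <- n %/% batch_size
      for (b in seq_len(n_batch)) {
        take <- ord[((b - 1) * batch_size + 1):(b * batch_size)]
        x_real <- x_all[, , , take, drop = FALSE]
        z <- matrix(stats::rnorm(latent * batch_size), latent, batch_size)
        gfw <- nn_forward(gan$generator$net, z, training = TRUE)
        gan$generator$net <- gfw$net
        x_fake <- gfw$out

        # --- discriminator step on the joint real+fake batch
        xb <- array(c(x_real, x_fake), dim = c(dim(x_real)[1:3],
                                               2L * batch_size))
        tb <- c(rep(1, batch_size), rep(0, batch_size))
        dfw <- nn_forward(gan$discriminator$net, xb, training = TRUE)
        gan$discriminator$net <- dfw$net
        p <- sigmoid(as.vector(dfw$out))
        d_mon <- bce(p, tb)  # mean BCE over the real and fake half-batches
        dz <- matrix((p - tb) / length(tb), 1)
        dbk <- nn_backward(gan$discriminator$net, dfw$caches, dz)
        gan$discriminator$net <- nn_adam_step(gan$discriminator$net,
                                              dbk$grads, lr, beta1)

        # --- generator step: push the same fake batch through the updated
        # discriminator and backpropagate into the cached generator pass
        # (the generator's parameters are untouched since that pass)
        dfw2 <- nn_forward(gan$discriminator$net, x_fake, training = FALSE)
        p2 <- sigmoid(as.vector(dfw2$out))
        g_mon <- bce(p2, rep(1, batch_size))
        dz2 <- matrix((p2 - 1) / batch_size, 1)
        dbk2 <- nn_backward(gan$discriminator$net, dfw2$caches, dz2)
        gbk <- nn_backward(gan$generator$net, gfw$caches, dbk2$dx)
        gan$generator$net <- nn_adam_step(gan$generator$net, gbk$grads,
                                          lr, beta1)

        if (!is.finite(d_mon) || !is.finite(g_mon))
          stop(sprintf("non-finite loss at epoch %d batch %d (d=%g, g=%g)",
                       epoch, b, d_mon, g_mon))
        d_hist <- c(d_hist, d_mon)
        g_hist <- c(g_hist, g_mon)
        st$batch <- st$batch + 1L
        st$violation_streak <- if (d_mon > g_mon) st$violation_streak + 1L
                               else 0L
        if (st$violation_streak >= k) {
          st$stopped_early <- TRUE
          break
        }
      }
      st$epoch <- epoch
      # probe-batch invariants: shape and tanh range of generated images
      stopifnot(identical(dim(x_fake)[1:3],
                          c(gan$generator$out_size, gan$generator$out_size, 3L)),
                max(abs(x_fake)) <= 1)
      if (verbose)
        message(sprintf("epoch %3d  d=%.4f g=%.4f streak=%d", epoch,
                        d_mon, g_mon, st$violation_streak))
      if (st$stopped_early) break
    }
  })
  st$history <- data.frame(d_loss = d_hist, g_loss = g_hist)
  gan$train_state <- st
  gan
}

#' Draw synthetic spectrogram images from a GAN
#'
#' Latent vectors are drawn from the standard Gaussian `N(0, I)`; samples
#' carry `source = "generated"` and the class label the GAN was trained on.
#' Sampling from an untrained generator is allowed (useful for probes) and
#' is flagged with a message.
#'
#' @param gan a `gan_model`.
#' @param n number of samples (> 0).
#' @param seed RNG seed for the latent draws.
#' @return List of `n` [spectrogram_image()] objects.
#' @export
sample_gan <- function(gan, n, seed = 1L) {
  if (n <= 0) stop("n must be positive")
  if (gan$train_state$batch == 0L)
    message("sampling from an untrained generator")
  latent <- gan$generator$config$latent_dim
  with_seed(seed, {
    z <- matrix(stats::rnorm(latent * n), latent, n)
    x <- generator_forward(gan$generator, z, training = FALSE)
    lapply(seq_len(n), function(i)
      spectrogram_image(x[, , , i], label = gan$class_label,
                        source = "generated"))
  })
}
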