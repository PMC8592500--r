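# ---- convolutional epileptic seizure predictor -----------------------------

#' CESP configuration
#'
#' A small CNN for pre-ictal vs interictal classification of spectrogram
#' images: three blocks of 3x3 stride-1 convolution + ReLU + 2x2 max
#' pooling with 126, 64 and 64 filters, then a 32-unit fully connected
#' layer with sigmoid activation and a 2-unit sigmoid output trained with
#' one-hot binary cross-entropy under Adam. The 126-filter width of the
#' first block is kept as printed in the source architecture (not rounded
#' to 128); override it here if desired.
#'
#' @param conv_filters filter counts for the three blocks.
#' @param kernel convolution kernel side (default 3).
#' @param fc_sizes fully connected widths; the last entry is the number of
#'   classes and must be 2.
#' @param lr Adam learning rate (default 1e-4).
#' @param epochs training epochs (default 50).
#' @param batch_size mini-batch size.
#' @param folds cross-validation folds (default 10).
#' @param patience early-stopping patience on validation loss, in epochs.
#' @param seed RNG seed.
#' @return A `cesp_config` object.
#' @export
cesp_config <- function(conv_filters = c(126, 64, 64), kernel = 3,
                        fc_sizes = c(32, 2), lr = 1e-4, epochs = 50,
                        batch_size = 32, folds = 10, patience = 10,
                        seed = 1L) {
  stopifnot(length(conv_filters) == 3, folds >= 2,
            fc_sizes[length(fc_sizes)] == 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), fc_sizes = as.integer(fc_sizes),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 folds = as.integer(folds), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "cesp_config")
}

#' Build the CESP network
#'
#' @param cfg a [cesp_config()].
#' @param in_size image side S; must be divisible by 8 (three 2x2 pools).
#' @return A `cesp_model` with untrained parameters.
#' @export
build_cesp <- function(cfg, in_size) {
  if (in_size %% 8L != 0)
    stop(sprintf("in_size %d is not divisible by 2^3 (three max-pools)",
                 in_size))
  layers <- list()
  c_prev <- 3L
  for (f in cfg$conv_filters) {
    layers <- c(layers, list(nn_conv(cfg$kernel, c_prev, f, stride = 1),
                             nn_act("relu"), nn_maxpool()))
    c_prev <- f
  }
  side <- in_size / 8L
  d_in <- side * side * c_prev
  layers <- c(layers, list(nn_flatten()))
  for (i in seq_along(cfg$fc_sizes)) {
    layers <- c(layers, list(nn_dense(d_in, cfg$fc_sizes[i])))
    if (i < length(cfg$fc_sizes)) layers <- c(layers, list(nn_act("sigmoid")))
    d_in <- cfg$fc_sizes[i]
  }
  structure(list(net = nn_network(layers), config = cfg,
                 in_size = as.integer(in_size), trained = FALSE,
                 fold_metrics = NULL, history = NULL),
            class = "cesp_model")
}

.name_units <- function(p) { rownames(p) <- .sg_labels; p }

# one-hot targets, row 1 = interictal, row 2 = preictal
.one_hot <- function(labels) {
  rbind(interictal = as.numeric(labels == "interictal"),
        preictal = as.numeric(labels == "preictal"))
}

.cesp_fit <- function(model, x, y, epochs, x_val = NULL, y_val = NULL,
                      verbose = FALSE) {
  cfg <- model$config
  n <- dim(x)[4]
  bs <- min(cfg$batch_size, n)
  best <- list(loss = Inf, net = model$net, since = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tl <- 0
    nb <- max(1L, n %/% bs)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1) * bs + 1):min(b * bs, n)]
      xb <- x[, , , take, drop = FALSE]
      tb <- y[, take, drop = FALSE]
      fw <- nn_forward(model$net, xb, training = TRUE)
      model$net <- fw$net
      p <- sigmoid(fw$out)
      tl <- tl + bce(p, tb)
      dz <- (p - tb) / ncol(tb)
      bk <- nn_backward(model$net, fw$caches, dz)
      model$net <- nn_adam_step(model$net, bk$grads, cfg$lr)
    }
    vl <- NA_real_
    if (!is.null(x_val)) {
      pv <- sigmoid(nn_forward(model$net, x_val)$out)
      vl <- bce(pv, y_val)
      if (vl < best$loss) best <- list(loss = vl, net = model$net, since = 0L)
      else best$since <- best$since + 1L
      if (best$since >= cfg$patience) {
        model$net <- best$net
        hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                       val_loss = vl))
        break
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %3d train %.4f val %.4f", ep,
                                 tl / nb, vl))
  }
  model$history <- hist
  model
}

#' Train the CESP with stratified k-fold cross-validation
#'
#' Splits the training data into `folds` stratified folds (default 10, i.e.
#' 90% train / 10% validation per fold), records per-fold validation
#' accuracy and loss, then refits on the full training data for deployment.
#' Fold assignments are reproducible under `cfg$seed`.
#'
#' @param images list of labeled [spectrogram_image()] objects containing
#'   both classes.
#' @param cfg a [cesp_config()].
#' @param in_size image side; inferred from the first image when `NULL`.
#' @param cv run the cross-validation loop (set `FALSE` to refit only).
#' @param verbose print per-epoch losses.
#' @return A trained `cesp_model` with `fold_metrics` (data frame of fold,
#'   validation accuracy, validation loss) when `cv = TRUE`.
#' @export
train_cesp <- function(images, cfg = cesp_config(), in_size = NULL,
                       cv = TRUE, verbose = FALSE) {
  labels <- image_labels(images)
  if (length(unique(labels)) < 2L)
    stop("training data must contain both classes")
  if (length(images) < cfg$folds)
    stop("need at least as many images as folds")
  if (is.null(in_size)) in_size <- dim(images[[1]]$pixels)[1]
  x <- image_tensor(images)
  y <- .one_hot(labels)
  fold_metrics <- NULL
  with_seed(cfg$seed, {
    folds <- integer(length(images))
    for (lb in unique(labels)) {       # stratified assignment
      idx <- which(labels == lb)
      folds[idx] <- sample(rep_len(seq_len(cfg$folds), length(idx)))
    }
    if (cv) {
      fold_metrics <- do.call(rbind, lapply(seq_len(cfg$folds), function(f) {
        tr <- folds != f
        m <- build_cesp(cfg, in_size)
        m <- .cesp_fit(m, x[, , , tr, drop = FALSE], y[, tr, drop = FALSE],
                       cfg$epochs,
                       x_val = x[, , , !tr, drop = FALSE],
                       y_val = y[, !tr, drop = FALSE])
        pv <- .name_units(sigmoid(nn_forward(m$net,
                                             x[, , , !tr, drop = FALSE])$out))
        pred <- ifelse(pv["preictal", ] >= pv["interictal", ],
                       "preictal", "interictal")
        data.frame(fold = f, val_accuracy = mean(pred == labels[!tr]),
                   val_loss = bce(pv, y[, !tr, drop = FALSE]))
      }))
    }
    model <- build_cesp(cfg, in_size)
    model <- .cesp_fit(model, x, y, cfg$epochs, verbose = verbose)
    model$trained <- TRUE
    model$fold_metrics <- fold_metrics
    model$fold_assignments <- folds
    model
  })
}

#' Pre-ictal probabilities from a trained CESP
#'
#' The ranking statistic is the raw sigmoid score of the pre-ictal output
#' unit; the pairwise-normalized score
#' `p_preictal / (p_preictal + p_interictal)` is also returned (the two
#' sigmoid units are independent, so scores need not sum to one).
#'
#' @param model a trained `cesp_model`.
#' @param images list of [spectrogram_image()] objects (may be empty).
#' @return Data frame with columns `p_preictal`, `p_interictal`,
#'   `p_normalized`, one row per image.
#' @export
predict_cesp <- function(model, images) {
  stopifnot(inherits(model, "cesp_model"))
  if (!length(images))
    return(data.frame(p_preictal = numeric(0), p_interictal = numeric(0),
                      p_normalized = numeric(0)))
  d <- dim(images[[1]]$pixels)[1]
  if (d != model$in_size)
    stop(sprintf("image side %d does not match the model's input size %d",
                 d, model$in_size))
  x <- image_tensor(images)
  p <- .name_units(sigmoid(nn_forward(model$net, x)$out))
  data.frame(p_preictal = p["preictal", ], p_interictal = p["interictal", ],
             p_normalized = p["preictal", ] /
               (p["preictal", ] + p["interictal", ]))
}

# spatial sides after each pooling stage, for architecture introspection
cesp_spatial_sides <- function(in_size) in_size / 2^(1:3)
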