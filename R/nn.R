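#' @useDynLib spectrogan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- small neural-network engine -------------------------------------------
#
# Networks are lists of layers; activations flow as (d x N) matrices for
# dense stages and (H, W, C, N) arrays for convolutional stages. Convolution
# kernels live in src/conv_ops.cpp (im2col + single-precision GEMM); the
# orchestration, batch norm, activations and Adam are plain R. All layers use
# "same" padding; strides follow the TensorFlow convention, so a stride-2
# conv halves (ceil) the side and a stride-2 transposed conv doubles it.

sigmoid <- function(x) 1 / (1 + exp(-x))

# broadcast a per-channel vector over an (H, W, C, N) array
.bc <- function(v, hw) rep(v, each = hw)

# per-channel sum / mean over (H, W, N) of an (H, W, C, N) array, avoiding
# apply()'s aperm copies
.chan_sum <- function(a) {
  d <- dim(a)
  rowSums(matrix(colSums(matrix(a, d[1] * d[2])), d[3], d[4]))
}
.chan_mean <- function(a) .chan_sum(a) / (dim(a)[1] * dim(a)[2] * dim(a)[4])

.same_pad <- function(side, k, stride) {
  out <- ceiling(side / stride)
  pt <- max((out - 1L) * stride + k - side, 0L)
  list(out = as.integer(out), pad = as.integer(pt %/% 2))
}

.init_w <- function(dims, init_sd = NULL) {
  fan_in <- prod(dims[-length(dims)])
  sd <- if (is.null(init_sd)) sqrt(2 / fan_in) else init_sd
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}

nn_dense <- function(d_in, d_out, init_sd = NULL) {
  list(type = "dense",
       params = list(W = matrix(.init_w(c(d_in, d_out), init_sd), d_in, d_out),
                     b = numeric(d_out)))
}

nn_conv <- function(k, c_in, c_out, stride = 1L, init_sd = NULL) {
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       params = list(W = .init_w(c(k, k, c_in, c_out), init_sd),
                     b = numeric(c_out)))
}

# stride-2 transposed convolution: (h, w, c_in) -> (2h, 2w, c_out).
# Weight layout (k, k, c_out, c_in): the kernel of the adjoint convolution.
nn_convt <- function(k, c_in, c_out, init_sd = NULL) {
  list(type = "convt", k = as.integer(k),
       pad = as.integer(max(k - 2L, 0L) %/% 2L),
       params = list(W = .init_w(c(k, k, c_out, c_in), init_sd),
                     b = numeric(c_out)))
}

nn_bn <- function(c, momentum = 0.99, eps = 1e-5) {
  list(type = "bn", momentum = momentum, eps = eps,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       running_mean = numeric(c), running_var = rep(1, c))
}

nn_act <- function(kind = c("relu", "lrelu", "tanh", "sigmoid"), alpha = 0.2) {
  list(type = "act", kind = match.arg(kind), alpha = alpha)
}

nn_reshape <- function(shape) list(type = "reshape", shape = as.integer(shape))
nn_flatten <- function() list(type = "flatten")
nn_maxpool <- function() list(type = "maxpool")

nn_network <- function(layers) structure(list(layers = layers, t = 0L),
                                         class = "sg_network")

nn_n_params <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (is.null(l$params)) 0L else sum(vapply(l$params, length, 1L))
  }, 1L))
}

.layer_fwd <- function(l, x, training) {
  switch(l$type,
    dense = {
      y <- crossprod(l$params$W, x) + l$params$b
      list(y = y, cache = list(x = x))
    },
    conv = {
      d <- dim(x)
      g <- .same_pad(d[1], l$k, l$stride)
      gw <- .same_pad(d[2], l$k, l$stride)
      y <- cpp_conv_fwd(x, l$params$W, l$stride, g$pad, g$out, gw$out)
      y <- y + .bc(l$params$b, g$out * gw$out)
      list(y = y, cache = list(x = x, pad = g$pad))
    },
    convt = {
      d <- dim(x)
      y <- cpp_conv_bwd_data(x, l$params$W, 2L * d[1], 2L * d[2], 2L, l$pad)
      y <- y + .bc(l$params$b, 4L * d[1] * d[2])
      list(y = y, cache = list(x = x))
    },
    bn = .bn_fwd(l, x, training),
    act = {
      y <- switch(l$kind,
        relu = pmax(x, 0),
        lrelu = pmax(x, 0) + l$alpha * pmin(x, 0),
        tanh = tanh(x),
        sigmoid = sigmoid(x))
      if (!is.null(dim(x))) dim(y) <- dim(x)
      list(y = y, cache = list(x = x, y = y))
    },
    maxpool = {
      d <- dim(x)
      r <- cpp_maxpool_fwd(x)
      list(y = r$y, cache = list(idx = r$idx, H = d[1], W = d[2]))
    },
    reshape = {
      n <- ncol(x)
      y <- x
      dim(y) <- c(l$shape, n)
      list(y = y, cache = list(d_in = dim(x)))
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4])
      list(y = y, cache = list(d_in = d))
    },
    stop("unknown layer type: ", l$type))
}

.bn_fwd <- function(l, x, training) {
  d <- dim(x)
  conv <- length(d) == 4L
  if (training) {
    if (conv) {
      m <- d[1] * d[2] * d[4]
      mu <- .chan_mean(x)
      ctr <- x - .bc(mu, d[1] * d[2])
      va <- .chan_mean(ctr * ctr)
      invstd <- 1 / sqrt(va + l$eps)
      xhat <- ctr * .bc(invstd, d[1] * d[2])
      y <- xhat * .bc(l$params$gamma, d[1] * d[2]) +
        .bc(l$params$beta, d[1] * d[2])
    } else {
      m <- ncol(x)
      mu <- rowMeans(x)
      ctr <- x - mu
      va <- rowMeans(ctr * ctr)
      invstd <- 1 / sqrt(va + l$eps)
      xhat <- ctr * invstd
      y <- xhat * l$params$gamma + l$params$beta
    }
    list(y = y, cache = list(xhat = xhat, invstd = invstd, m = m, conv = conv),
         running = list(mean = l$momentum * l$running_mean + (1 - l$momentum) * mu,
                        var = l$momentum * l$running_var + (1 - l$momentum) * va))
  } else {
    invstd <- 1 / sqrt(l$running_var + l$eps)
    if (conv) {
      hw <- d[1] * d[2]
      y <- (x - .bc(l$running_mean, hw)) * .bc(invstd, hw) *
        .bc(l$params$gamma, hw) + .bc(l$params$beta, hw)
    } else {
      y <- (x - l$running_mean) * invstd * l$params$gamma + l$params$beta
    }
    list(y = y, cache = NULL)
  }
}

# Forward pass. Returns the output, per-layer caches for backprop, and the
# network with refreshed batch-norm running statistics (when training).
nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- .layer_fwd(net$layers[[i]], x, training)
    x <- r$y
    caches[[i]] <- r$cache
    if (!is.null(r$running)) {
      net$layers[[i]]$running_mean <- r$running$mean
      net$layers[[i]]$running_var <- r$running$var
    }
  }
  list(out = x, caches = caches, net = net)
}

.layer_bwd <- function(l, cache, dy) {
  switch(l$type,
    dense = list(dx = l$params$W %*% dy,
                 grads = list(W = cache$x %*% t(dy), b = rowSums(dy))),
    conv = {
      d <- dim(cache$x)
      list(dx = cpp_conv_bwd_data(dy, l$params$W, d[1], d[2], l$stride,
                                  cache$pad),
           grads = list(W = cpp_conv_bwd_filter(dy, cache$x, l$k, l$stride,
                                                cache$pad),
                        b = .chan_sum(dy)))
    },
    convt = {
      d <- dim(cache$x)
      list(dx = cpp_conv_fwd(dy, l$params$W, 2L, l$pad, d[1], d[2]),
           grads = list(W = cpp_conv_bwd_filter(cache$x, dy, l$k, 2L, l$pad),
                        b = .chan_sum(dy)))
    },
    bn = .bn_bwd(l, cache, dy),
    act = {
      dx <- switch(l$kind,
        relu = dy * (cache$x > 0),
        lrelu = dy * (l$alpha + (1 - l$alpha) * (cache$x > 0)),
        tanh = dy * (1 - cache$y^2),
        sigmoid = dy * cache$y * (1 - cache$y))
      if (!is.null(dim(cache$x))) dim(dx) <- dim(cache$x)
      list(dx = dx, grads = NULL)
    },
    maxpool = list(dx = cpp_maxpool_bwd(dy, cache$idx, cache$H, cache$W),
                   grads = NULL),
    reshape = { dim(dy) <- cache$d_in; list(dx = dy, grads = NULL) },
    flatten = { dim(dy) <- cache$d_in; list(dx = dy, grads = NULL) })
}

.bn_bwd <- function(l, cache, dy) {
  xhat <- cache$xhat; m <- cache$m
  if (cache$conv) {
    d <- dim(xhat); hw <- d[1] * d[2]
    dgamma <- .chan_sum(dy * xhat)
    dbeta <- .chan_sum(dy)
    dxhat <- dy * .bc(l$params$gamma, hw)
    s1 <- .chan_sum(dxhat)
    s2 <- .chan_sum(dxhat * xhat)
    dx <- (.bc(cache$invstd, hw) / m) *
      (m * dxhat - .bc(s1, hw) - xhat * .bc(s2, hw))
  } else {
    dgamma <- rowSums(dy * xhat)
    dbeta <- rowSums(dy)
    dxhat <- dy * l$params$gamma
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * xhat)
    dx <- (cache$invstd / m) * (m * dxhat - s1 - xhat * s2)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# Backward pass through all layers; returns per-layer gradient lists and the
# gradient w.r.t. the network input.
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- .layer_bwd(net$layers[[i]], caches[[i]], dout)
    dout <- r$dx
    if (!is.null(r$grads)) grads[[i]] <- r$grads
  }
  list(grads = grads, dx = dout)
}

nn_adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  net$t <- net$t + 1L
  bc1 <- 1 - beta1^net$t
  bc2 <- 1 - beta2^net$t
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- net$layers[[i]]
    if (is.null(l[["m"]])) {
      l$m <- lapply(l$params, function(p) p * 0)
      l$v <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(g)) {
      l$m[[nm]] <- beta1 * l$m[[nm]] + (1 - beta1) * g[[nm]]
      l$v[[nm]] <- beta2 * l$v[[nm]] + (1 - beta2) * g[[nm]]^2
      upd <- (l$m[[nm]] / bc1) / (sqrt(l$v[[nm]] / bc2) + eps)
      l$params[[nm]] <- l$params[[nm]] - lr * upd
    }
    net$layers[[i]] <- l
  }
  net
}

# binary cross-entropy on sigmoid probabilities, summed over output units,
# averaged over the batch; probabilities clamped away from {0, 1}
bce <- function(p, target, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  n <- if (is.matrix(p)) ncol(p) else length(p)
  -sum(target * log(p) + (1 - target) * log(1 - p)) / n
}
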