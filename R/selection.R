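# ---- one-class SVM screening of generated samples --------------------------

#' Selector configuration
#'
#' Hyperparameters of the nu-one-class SVM used to accept or reject
#' generated spectrograms, and of the feature map feeding it. `nu` bounds
#' the fraction of training points treated as outliers; `gamma` is the RBF
#' kernel width in `K(x, y) = exp(-gamma * ||x - y||^2)`.
#'
#' @param nu fraction in `(0, 1]` (default 0.1).
#' @param gamma positive kernel width, or `"scale"` for the
#'   `1 / (d * var(features))` heuristic.
#' @param feature_downsample side length for bilinear downsampling before
#'   flattening (default 16, i.e. 256 features). The coarse scale keys the
#'   novelty decision to band-level spectral layout rather than pixel
#'   texture; see the package vignette for the rationale.
#' @return A `selector_config` object.
#' @export
selector_config <- function(nu = 0.1, gamma = "scale",
                            feature_downsample = 16) {
  stopifnot(nu > 0, nu <= 1)
  if (is.numeric(gamma)) stopifnot(gamma > 0)
  structure(list(nu = nu, gamma = gamma,
                 feature_downsample = as.integer(feature_downsample)),
            class = "selector_config")
}

#' Feature vector of a spectrogram image
#'
#' Averages the three (replicated) image channels, downsamples bilinearly
#' to `feature_downsample` squared pixels and flattens column-major.
#' Deterministic; images differing only in their replicated channel copies
#' map to identical features.
#'
#' @param img a [spectrogram_image()].
#' @param cfg a [selector_config()].
#' @return Numeric feature vector of length `feature_downsample^2`.
#' @export
featurize <- function(img, cfg = selector_config()) {
  m <- (img$pixels[, , 1] + img$pixels[, , 2] + img$pixels[, , 3]) / 3
  d <- cfg$feature_downsample
  if (d != nrow(m)) m <- EBImage::resize(m, w = d, h = d, filter = "bilinear")
  as.vector(m)
}

.feature_matrix <- function(x, cfg) {
  if (is.matrix(x)) return(x)
  t(vapply(x, featurize, numeric(cfg$feature_downsample^2), cfg = cfg))
}

#' Fit a one-class SVM on real spectrograms
#'
#' Solves the nu-one-class SVM problem (separating the data from the origin
#' in RBF feature space) via libsvm. The fitted model stores the support
#' vectors, their coefficients `beta_i`, the offset `rho` and the kernel
#' width `gamma`, so the decision function
#' `sign(sum_i beta_i K(x_i, x) - rho)` can be evaluated directly.
#'
#' @param real list of [spectrogram_image()] objects (>= 10), or a numeric
#'   feature matrix (rows = observations) to use verbatim.
#' @param cfg a [selector_config()].
#' @return A `selector_model`.
#' @export
fit_ocsvm <- function(real, cfg = selector_config()) {
  X <- .feature_matrix(real, cfg)
  if (nrow(X) < 10) stop("need at least 10 training samples")
  if (max(apply(X, 2, stats::var)) < 1e-12)
    stop("features are (near-)identical across training samples; ",
         "add jitter or check the inputs")
  gamma <- if (identical(cfg$gamma, "scale")) 1 / (ncol(X) * stats::var(as.vector(X)))
           else cfg$gamma
  fit <- e1071::svm(x = X, y = NULL, type = "one-classification",
                    kernel = "radial", nu = cfg$nu, gamma = gamma,
                    scale = FALSE, fitted = FALSE, tolerance = 1e-6)
  structure(list(fit = fit, support_vectors = fit$SV,
                 coefficients = as.vector(fit$coefs), rho = fit$rho,
                 gamma = gamma, config = cfg, n_features = ncol(X)),
            class = "selector_model")
}

#' Decision values of a fitted selector
#'
#' `sum_i beta_i K(x_i, x) - rho`; non-negative values are inliers.
#'
#' @param model a `selector_model`.
#' @param x feature matrix (rows = observations) or list of images.
#' @return Numeric vector of decision values.
#' @export
selector_decision <- function(model, x) {
  X <- .feature_matrix(x, model$config)
  if (!is.finite(model$rho)) {
    # nu = 1 boundary: the offset diverges and every point is an outlier
    return(rep(-model$rho, nrow(X)))
  }
  pr <- stats::predict(model$fit, X, decision.values = TRUE)
  as.vector(attr(pr, "decision.values"))
}

#' Screen generated samples with a fitted one-class SVM
#'
#' Partitions the inputs by the sign of the decision function: accepted
#' samples (decision >= 0) are returned with `accepted = TRUE`, the rest
#' rejected. An empty input yields an empty result with acceptance rate 0.
#'
#' @param model a `selector_model` from [fit_ocsvm()].
#' @param generated list of [spectrogram_image()] objects.
#' @return A `selection_result`: list with `accepted`, `rejected`,
#'   `acceptance_rate` and the decision values.
#' @export
filter_samples <- function(model, generated) {
  stopifnot(inherits(model, "selector_model"))
  if (!length(generated))
    return(structure(list(accepted = list(), rejected = list(),
                          acceptance_rate = 0, decision = numeric(0)),
                     class = "selection_result"))
  dec <- selector_decision(model, generated)
  keep <- dec >= 0
  accepted <- lapply(which(keep), function(i) {
    im <- generated[[i]]; im$accepted <- TRUE; im
  })
  rejected <- lapply(which(!keep), function(i) {
    im <- generated[[i]]; im$accepted <- FALSE; im
  })
  structure(list(accepted = accepted, rejected = rejected,
                 acceptance_rate = mean(keep), decision = dec),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d accepted / %d total (rate %.3f)\n",
              length(x$accepted), length(x$accepted) + length(x$rejected),
              x$acceptance_rate))
  invisible(x)
}
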