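# ---- segment -> spectrogram image pipeline ---------------------------------

#' Preprocessing configuration
#'
#' Controls the conversion of EEG segments into normalized spectrogram
#' images: power-line noise removal, per-channel short-time Fourier
#' transform (STFT), vertical concatenation of channel spectrograms, and
#' resize to a square image.
#'
#' @param window_s STFT window length in seconds (default 60, i.e. 1 min).
#' @param overlap window overlap fraction in `[0, 1)` (default 0).
#' @param out_size output image side S in pixels (default 256).
#' @param line_freq mains frequency in Hz; determines the default notch
#'   bands (fundamental +/- 3 Hz and first harmonic +/- 3 Hz, i.e.
#'   47-53/97-103 Hz for 50 Hz mains and 57-63/117-123 Hz for 60 Hz).
#' @param notch_bands optional list of `c(lo, hi)` stop bands overriding
#'   the default; bands must lie strictly inside `(0, fs/2)`.
#' @param filter_order Butterworth order per stop band (default 4); the
#'   filter is applied forward-backward, so the effective attenuation is
#'   doubled and the phase response is zero.
#' @param log_transform take `log(1 + magnitude)` before resizing.
#' @param normalize normalization scheme; `"minmax"` maps each image to
#'   `[-1, 1]` (a constant image maps to -1 by convention).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(window_s = 60, overlap = 0, out_size = 256,
                              line_freq = 50, notch_bands = NULL,
                              filter_order = 4, log_transform = TRUE,
                              normalize = "minmax") {
  stopifnot(overlap >= 0, overlap < 1, out_size >= 8, window_s > 0,
            normalize == "minmax")
  structure(list(window_s = window_s, overlap = overlap,
                 out_size = as.integer(out_size), line_freq = line_freq,
                 notch_bands = notch_bands, filter_order = filter_order,
                 log_transform = isTRUE(log_transform),
                 normalize = normalize),
            class = "preprocess_config")
}

.notch_bands_for <- function(cfg, fs) {
  bands <- cfg$notch_bands
  if (is.null(bands))
    bands <- list(c(cfg$line_freq - 3, cfg$line_freq + 3),
                  c(2 * cfg$line_freq - 3, 2 * cfg$line_freq + 3))
  keep <- list()
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    if (b[2] >= fs / 2) {
      if (i == 1L)
        stop(sprintf("fundamental notch band [%g, %g] reaches Nyquist (%g Hz)",
                     b[1], b[2], fs / 2))
      message(sprintf("skipping notch band [%g, %g] Hz: above Nyquist (%g Hz)",
                      b[1], b[2], fs / 2))
      next
    }
    if (b[1] <= 0) stop("notch band lower edge must be > 0")
    keep[[length(keep) + 1L]] <- b
  }
  keep
}

#' Remove power-line noise from a segment
#'
#' Applies a zero-phase (forward-backward) Butterworth band-stop filter for
#' each configured notch band to every channel. Harmonic bands that exceed
#' the Nyquist frequency are skipped with a message; a fundamental band at
#' or above Nyquist is an error.
#'
#' @param seg an [eeg_segment()].
#' @param cfg a [preprocess_config()].
#' @return The filtered [eeg_segment()], same shape and sampling rate.
#' @export
remove_line_noise <- function(seg, cfg) {
  stopifnot(inherits(seg, "eeg_segment"))
  bands <- .notch_bands_for(cfg, seg$fs)
  x <- seg$samples
  for (b in bands) {
    bt <- signal::butter(cfg$filter_order, b / (seg$fs / 2), type = "stop")
    for (ch in seq_len(nrow(x)))
      x[ch, ] <- signal::filtfilt(bt, x[ch, ])
  }
  seg$samples <- x
  seg
}

#' Magnitude STFT of one channel
#'
#' Hann-windowed short-time Fourier transform; FFT length equals the window
#' sample count and the phase is discarded. With zero overlap the number of
#' window columns is `floor(length(x) / fs / window_s)`.
#'
#' @param x numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param cfg a [preprocess_config()].
#' @return Magnitude matrix, frequency bins x windows
#'   (`floor(wlen/2) + 1` non-negative-frequency bins).
#' @export
stft_channel <- function(x, fs, cfg) {
  wlen <- round(cfg$window_s * fs)
  if (length(x) < wlen)
    stop(sprintf("signal (%d samples) shorter than one %g s window (%d samples)",
                 length(x), cfg$window_s, wlen))
  hop <- max(1L, round(wlen * (1 - cfg$overlap)))
  n_win <- floor((length(x) - wlen) / hop) + 1L
  win <- signal::hanning(wlen)
  starts <- (seq_len(n_win) - 1L) * hop
  frames <- vapply(starts, function(s) x[(s + 1):(s + wlen)] * win,
                   numeric(wlen))
  spec <- Mod(stats::mvfft(frames))
  spec[seq_len(floor(wlen / 2) + 1L), , drop = FALSE]
}

.minmax_pm1 <- function(m) {
  r <- range(m)
  if (r[2] - r[1] < .Machine$double.eps * max(1, abs(r[2])))
    return(array(-1, dim = dim(m)))  # constant image -> -1 by convention
  2 * (m - r[1]) / (r[2] - r[1]) - 1
}

#' A normalized spectrogram image
#'
#' The unit flowing into every model: an `S x S x 3` array with values in
#' `[-1, 1]`, a class label, and provenance (real vs generated).
#'
#' @param pixels `S x S x 3` numeric array in `[-1, 1]`.
#' @param label `"preictal"` or `"interictal"`.
#' @param source `"real"` or `"generated"`.
#' @param subject_id subject identifier.
#' @param t_start segment start time in seconds (`NA` for generated images).
#' @param accepted logical flag set by the one-class SVM selector.
#' @return A `spectrogram_image` object.
#' @export
spectrogram_image <- function(pixels, label, source = "real",
                              subject_id = "sim", t_start = NA_real_,
                              accepted = NA) {
  d <- dim(pixels)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L)
    stop("pixels must be an S x S x 3 array")
  if (!all(is.finite(pixels))) stop("pixels contain non-finite values")
  if (min(pixels) < -1 - 1e-9 || max(pixels) > 1 + 1e-9)
    stop("pixel values must lie in [-1, 1]")
  if (!label %in% .sg_labels)
    stop("label must be one of: ", paste(.sg_labels, collapse = ", "))
  structure(list(pixels = pixels, label = label, source = source,
                 subject_id = subject_id, t_start = t_start,
                 accepted = accepted),
            class = "spectrogram_image")
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> %dx%dx3, label=%s, source=%s%s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$label, x$source,
              if (!is.na(x$accepted)) sprintf(", accepted=%s", x$accepted) else ""))
  invisible(x)
}

#' Assemble per-channel spectrograms into one image
#'
#' Stacks the channel magnitude matrices along the frequency axis in channel
#' order, optionally applies `log(1 + m)`, resizes bilinearly to
#' `out_size x out_size`, min-max normalizes to `[-1, 1]`, and replicates
#' the result to 3 identical channels so the image is compatible with
#' RGB-shaped networks. The output shape is `(S, S, 3)` regardless of the
#' channel count or sampling rate of the input.
#'
#' @param per_channel list of magnitude matrices (freq bins x windows), one
#'   per channel, all with the same window count.
#' @param cfg a [preprocess_config()].
#' @inheritParams spectrogram_image
#' @return A [spectrogram_image()].
#' @export
assemble_image <- function(per_channel, cfg, label = "interictal",
                           source = "real", subject_id = "sim",
                           t_start = NA_real_) {
  ncols <- vapply(per_channel, ncol, 1L)
  if (length(unique(ncols)) != 1L)
    stop("channel ", which(ncols != ncols[1])[1],
         " has a mismatched window count (", ncols[which(ncols != ncols[1])[1]],
         " vs ", ncols[1], ")")
  stacked <- do.call(rbind, per_channel)
  if (cfg$log_transform) stacked <- log1p(stacked)
  S <- cfg$out_size
  resized <- EBImage::resize(stacked, w = S, h = S, filter = "bilinear")
  img <- .minmax_pm1(resized)
  pixels <- array(img, dim = c(S, S, 3))
  spectrogram_image(pixels, label, source, subject_id, t_start)
}

#' Preprocess a list of segments into spectrogram images
#'
#' Maps [remove_line_noise()], [stft_channel()] and [assemble_image()] over
#' the segments, preserving labels and provenance. Errors on individual
#' segments are rethrown with the segment index.
#'
#' @param segments list of [eeg_segment()] objects.
#' @param cfg a [preprocess_config()].
#' @param denoise apply the notch filter first (default TRUE).
#' @param quiet suppress the per-class count message.
#' @return List of [spectrogram_image()] objects.
#' @export
preprocess_dataset <- function(segments, cfg, denoise = TRUE, quiet = FALSE) {
  imgs <- lapply(seq_along(segments), function(i) {
    tryCatch({
      seg <- segments[[i]]
      if (denoise) seg <- remove_line_noise(seg, cfg)
      mats <- lapply(seq_len(nrow(seg$samples)), function(ch)
        stft_channel(seg$samples[ch, ], seg$fs, cfg))
      assemble_image(mats, cfg, label = seg$label, source = "real",
                     subject_id = seg$subject_id, t_start = seg$t_start)
    }, error = function(e) stop("segment ", i, ": ", conditionMessage(e),
                                call. = FALSE))
  })
  if (!quiet && length(imgs)) {
    tab <- table(vapply(imgs, function(im) im$label, ""))
    message("preprocessed ", length(imgs), " segments (",
            paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  }
  imgs
}

# Stack a list of spectrogram images into an (S, S, 3, N) tensor.
image_tensor <- function(images) {
  stopifnot(length(images) > 0)
  d <- dim(images[[1]]$pixels)
  x <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels
  x
}

image_labels <- function(images) vapply(images, function(im) im$label, "")
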