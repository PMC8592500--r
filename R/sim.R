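# ---- synthetic EEG generation ----------------------------------------------

.sg_labels <- c("interictal", "preictal")

# Deterministic sub-seed for item `i` of a dataset seeded with `seed`;
# keeps every draw below 2^31 so set.seed() accepts it on all platforms.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 69069 + i * 10007) %% 2147483646) + 1L
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.as_bands <- function(b) {
  if (is.null(b) || (is.data.frame(b) && nrow(b) == 0L))
    return(data.frame(center_hz = numeric(0), bw_hz = numeric(0),
                      amp = numeric(0)))
  if (is.data.frame(b)) {
    stopifnot(all(c("center_hz", "bw_hz", "amp") %in% names(b)))
    return(b[c("center_hz", "bw_hz", "amp")])
  }
  if (is.numeric(b)) b <- list(b)
  do.call(rbind, lapply(b, function(x) {
    stopifnot(length(x) == 3L)
    data.frame(center_hz = x[1], bw_hz = x[2], amp = x[3])
  }))
}

#' Configuration for the synthetic EEG generator
#'
#' Describes a two-class EEG-like signal model: a `1/f^alpha` background,
#' class-specific narrow-band oscillations, mains (power-line) interference,
#' and white measurement noise. The two classes (pre-ictal vs interictal)
#' differ only through their band parameter sets, which makes the class
#' structure learnable from band power while everything else is shared.
#'
#' @param n_channels number of electrodes.
#' @param fs sampling rate in Hz; must exceed twice the highest band center.
#' @param segment_len segment duration in seconds.
#' @param preictal_bands,interictal_bands oscillatory band sets per class;
#'   a data frame with columns `center_hz`, `bw_hz`, `amp`, or a list of
#'   `c(center, bandwidth, amplitude)` triples.
#' @param background_exponent slope alpha of the `1/f^alpha` background.
#' @param background_amp standard deviation of the background component
#'   (0 disables it).
#' @param line_noise_freq mains frequency in Hz (50 or 60).
#' @param line_noise_amp amplitude of the mains sinusoid.
#' @param noise_sd standard deviation of additive white noise.
#' @param seed integer RNG seed; identical configuration and seed give
#'   bit-identical datasets.
#' @return A `sim_config` object.
#' @seealso [sim_preset()] for ready-made settings, [simulate_segment()],
#'   [simulate_dataset()], [simulate_timeline()].
#' @export
sim_config <- function(n_channels = 8, fs = 256, segment_len = 8,
                       preictal_bands = list(c(24, 4, 1.6), c(6, 2, 0.5)),
                       interictal_bands = list(c(10, 2, 1.6), c(6, 2, 0.5)),
                       background_exponent = 1, background_amp = 1,
                       line_noise_freq = 60, line_noise_amp = 0.5,
                       noise_sd = 0.5, seed = 1L) {
  cfg <- structure(list(
    n_channels = as.integer(n_channels), fs = fs, segment_len = segment_len,
    preictal_bands = .as_bands(preictal_bands),
    interictal_bands = .as_bands(interictal_bands),
    background_exponent = background_exponent,
    background_amp = background_amp,
    line_noise_freq = line_noise_freq, line_noise_amp = line_noise_amp,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_channels < 1L) stop("n_channels must be >= 1")
  if (cfg$segment_len <= 0) stop("segment_len must be positive")
  centers <- c(cfg$preictal_bands$center_hz, cfg$interictal_bands$center_hz)
  if (length(centers) && cfg$fs <= 2 * max(centers))
    stop(sprintf("fs = %g violates the Nyquist constraint for band center %g Hz",
                 cfg$fs, max(centers)))
  invisible(cfg)
}

#' Built-in simulation presets
#'
#' `"ieeg-like"` mimics a 16-electrode intracranial montage sampled at
#' 400 Hz with 50 Hz mains contamination and 10-minute segments;
#' `"scalp-like"` a 22-electrode scalp montage at 256 Hz with 60 Hz mains.
#' `"desk"` is a small 8-channel, 256 Hz, 8-second setting intended for
#' fast experimentation and unit tests.
#'
#' @param preset preset name.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @export
sim_preset <- function(preset = c("desk", "ieeg-like", "scalp-like"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "ieeg-like" = list(n_channels = 16, fs = 400, segment_len = 600,
                       line_noise_freq = 50),
    "scalp-like" = list(n_channels = 22, fs = 256, segment_len = 600,
                        line_noise_freq = 60),
    "desk" = list(n_channels = 8, fs = 256, segment_len = 8,
                  line_noise_freq = 60))
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_config, base)
}

#' A labeled multichannel EEG segment
#'
#' @param samples numeric matrix, channels x timepoints.
#' @param fs sampling rate in Hz.
#' @param label `"preictal"` or `"interictal"`.
#' @param channel_names optional channel labels.
#' @param subject_id subject identifier.
#' @param t_start segment start time in seconds from the recording origin.
#' @return An `eeg_segment` object.
#' @export
eeg_segment <- function(samples, fs, label, channel_names = NULL,
                        subject_id = "sim", t_start = 0) {
  if (!label %in% .sg_labels)
    stop("label must be one of: ", paste(.sg_labels, collapse = ", "))
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(samples)))
  structure(list(samples = samples, fs = fs, channel_names = channel_names,
                 label = label, subject_id = subject_id, t_start = t_start),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %d ch x %d samples @ %g Hz, label=%s, t=%gs\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$label, x$t_start))
  invisible(x)
}

.pink_noise <- function(n, alpha) {
  # FFT-shaped Gaussian noise with power spectrum ~ 1/f^alpha, unit sd
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(1, seq_len(n - 1))          # avoid DC blow-up
  f <- pmin(f, n - f + 1)            # mirror for the negative frequencies
  X <- X * f^(-alpha / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

.simulate_samples <- function(cfg, label, n_t) {
  t <- (seq_len(n_t) - 1) / cfg$fs
  bands <- if (label == "preictal") cfg$preictal_bands else cfg$interictal_bands
  phi_line <- stats::runif(1, 0, 2 * pi)
  out <- matrix(0, cfg$n_channels, n_t)
  for (ch in seq_len(cfg$n_channels)) {
    x <- numeric(n_t)
    if (cfg$background_amp > 0)
      x <- x + cfg$background_amp * .pink_noise(n_t, cfg$background_exponent)
    else stats::rnorm(n_t)  # keep the stream aligned across configurations
    if (nrow(bands)) {
      for (bi in seq_len(nrow(bands))) {
        n_osc <- 3L
        fr <- stats::runif(n_osc, bands$center_hz[bi] - bands$bw_hz[bi] / 2,
                           bands$center_hz[bi] + bands$bw_hz[bi] / 2)
        ph <- stats::runif(n_osc, 0, 2 * pi)
        am <- bands$amp[bi] / sqrt(n_osc) * stats::runif(n_osc, 0.9, 1.1)
        for (j in seq_len(n_osc))
          x <- x + am[j] * sin(2 * pi * fr[j] * t + ph[j])
      }
    }
    if (cfg$line_noise_amp > 0)
      x <- x + cfg$line_noise_amp * sin(2 * pi * cfg$line_noise_freq * t + phi_line)
    if (cfg$noise_sd > 0)
      x <- x + stats::rnorm(n_t, 0, cfg$noise_sd)
    out[ch, ] <- x
  }
  out
}

#' Simulate one EEG segment
#'
#' Each channel is the sum of a `1/f^alpha` background, the class's
#' narrow-band oscillators (random frequency within the band, random phase),
#' a mains sinusoid with a segment-wide random phase, and white noise.
#' Deterministic given `cfg$seed` and `segment_id`.
#'
#' @param cfg a [sim_config()].
#' @param label `"preictal"` or `"interictal"`.
#' @param subject_id subject identifier carried through the pipeline.
#' @param t_start segment start time (seconds).
#' @param segment_id integer used to derive the per-segment RNG sub-stream,
#'   so segment `i` of a dataset is reproducible in isolation.
#' @return An [eeg_segment()].
#' @export
simulate_segment <- function(cfg, label, subject_id = "sim", t_start = 0,
                             segment_id = 0L) {
  validate_sim_config(cfg)
  if (!label %in% .sg_labels)
    stop("invalid label '", label, "'; allowed labels: ",
         paste(.sg_labels, collapse = ", "))
  n_t <- round(cfg$segment_len * cfg$fs)
  samples <- with_seed(derive_seed(cfg$seed, segment_id),
                       .simulate_samples(cfg, label, n_t))
  eeg_segment(samples, cfg$fs, label, subject_id = subject_id,
              t_start = t_start)
}

#' Simulate a balanced two-class EEG dataset
#'
#' Emits `2 * n_per_class` segments in a fixed, documented order:
#' interictal/pre-ictal pairs, i.e. labels alternate starting with
#' interictal. Segment `i` receives `t_start = (i - 1) * segment_len` and
#' its own RNG sub-stream derived from `cfg$seed`.
#'
#' @inheritParams simulate_segment
#' @param n_per_class segments per class (>= 1).
#' @return A list of [eeg_segment()] objects.
#' @export
simulate_dataset <- function(cfg, n_per_class, subject_id = "sim") {
  validate_sim_config(cfg)
  stopifnot(n_per_class >= 1)
  n <- 2L * as.integer(n_per_class)
  labels <- rep(.sg_labels, n_per_class)
  lapply(seq_len(n), function(i) {
    simulate_segment(cfg, labels[i], subject_id = subject_id,
                     t_start = (i - 1) * cfg$segment_len, segment_id = i)
  })
}

#' Simulate a continuous recording timeline with seizures
#'
#' Places `n_seizures` onsets on a `duration_h`-hour timeline and extracts
#' labeled segments around them: pre-ictal segments from the window that
#' ends one seizure-prediction horizon (SPH) before each onset and spans one
#' seizure-occurrence period (SOP), interictal segments at least four hours
#' away from every onset. The onset list is returned as ground truth for
#' event-level alarm scoring with [alarm_evaluate()].
#'
#' @inheritParams simulate_segment
#' @param duration_h timeline duration in hours.
#' @param n_seizures number of seizure onsets.
#' @param sph_min seizure prediction horizon (minutes).
#' @param sop_min seizure occurrence period (minutes).
#' @param segments_per_seizure pre-ictal segments extracted per onset.
#' @param n_interictal interictal segments; defaults to the total pre-ictal
#'   count (12 when there are no seizures).
#' @return A `seizure_timeline`: list with `duration_h`, `seizure_onsets`
#'   (seconds, sorted), `segments`, `segment_index` (data frame of
#'   `t_start`, `label`), and the SPH/SOP used.
#' @export
simulate_timeline <- function(cfg, duration_h, n_seizures, sph_min = 10,
                              sop_min = 30, segments_per_seizure = 6,
                              n_interictal = NULL, subject_id = "sim") {
  validate_sim_config(cfg)
  dur <- duration_h * 3600
  sph <- sph_min * 60
  sop <- sop_min * 60
  seg <- cfg$segment_len
  n_seizures <- as.integer(n_seizures)
  if (n_seizures > 0) {
    first_min <- 4 * 3600 + 1800   # keep >= 30 min of usable interictal time
    gap <- sph + sop
    usable <- dur - first_min
    if (usable < n_seizures * gap * 1.2)
      stop(sprintf(paste0("cannot place %d seizures in %.1f h: each needs > ",
                          "%.0f s separation and interictal time must remain ",
                          ">= 4 h from every onset"), n_seizures, duration_h, gap))
    onsets <- with_seed(derive_seed(cfg$seed, 999999L), {
      base <- first_min + usable * seq_len(n_seizures) / n_seizures
      jit <- stats::runif(n_seizures, -0.05, 0.05) * usable / n_seizures
      sort(pmin(base + jit, dur - 1))
    })
    if (any(diff(onsets) <= gap)) onsets <- first_min + usable *
        seq_len(n_seizures) / n_seizures  # fall back to the even grid
  } else onsets <- numeric(0)

  idx <- data.frame(t_start = numeric(0), label = character(0))
  for (o in onsets) {
    w0 <- o - sph - sop
    w1 <- o - sph - seg
    ts <- if (w1 <= w0) w0 else seq(w0, w1, length.out = segments_per_seizure)
    idx <- rbind(idx, data.frame(t_start = ts, label = "preictal"))
  }
  if (is.null(n_interictal))
    n_interictal <- if (n_seizures > 0) n_seizures * segments_per_seizure else 12L
  # interictal candidates: segment must stay >= 4 h from every onset
  ok <- function(t) all(abs(c(t, t + seg) - rep(onsets, each = 2)) >= 4 * 3600) ||
    n_seizures == 0
  cand <- seq(0, dur - seg, length.out = max(200L, 4L * n_interictal))
  cand <- cand[vapply(cand, ok, TRUE)]
  if (!length(cand)) stop("no interictal time >= 4 h away from all onsets")
  ii <- cand[round(seq(1, length(cand), length.out = min(n_interictal,
                                                         length(cand))))]
  idx <- rbind(idx, data.frame(t_start = ii, label = "interictal"))
  idx <- idx[order(idx$t_start), ]
  rownames(idx) <- NULL

  segments <- lapply(seq_len(nrow(idx)), function(i) {
    simulate_segment(cfg, idx$label[i], subject_id = subject_id,
                     t_start = idx$t_start[i], segment_id = 500000L + i)
  })
  structure(list(duration_h = duration_h, seizure_onsets = onsets,
                 segments = segments, segment_index = idx,
                 sph_min = sph_min, sop_min = sop_min, config = cfg),
            class = "seizure_timeline")
}

#' @export
print.seizure_timeline <- function(x, ...) {
  cat(sprintf("<seizure_timeline> %g h, %d seizures, %d segments (%d preictal)\n",
              x$duration_h, length(x$seizure_onsets), nrow(x$segment_index),
              sum(x$segment_index$label == "preictal")))
  invisible(x)
}
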