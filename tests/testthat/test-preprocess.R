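make_sine_segment <- function(freq, fs = 256, secs = 10, channels = 1) {
  t <- (0:(fs * secs - 1)) / fs
  eeg_segment(matrix(rep(sin(2 * pi * freq * t), channels), nrow = channels,
                     byrow = TRUE), fs = fs, label = "interictal")
}

peak_power <- function(x, fs, freq) {
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, fast = FALSE)
  sp$spec[which.min(abs(sp$freq * fs - freq))]
}

test_that("the notch filter removes mains noise but spares nearby bands", {
  cfg <- preprocess_config(line_freq = 60)
  s60 <- make_sine_segment(60)
  out60 <- remove_line_noise(s60, cfg)
  atten60 <- 10 * log10(peak_power(s60$samples[1, ], 256, 60) /
                          peak_power(out60$samples[1, ], 256, 60))
  expect_gte(atten60, 20)

  s30 <- make_sine_segment(30)
  out30 <- remove_line_noise(s30, cfg)
  atten30 <- 10 * log10(peak_power(s30$samples[1, ], 256, 30) /
                          peak_power(out30$samples[1, ], 256, 30))
  expect_lte(abs(atten30), 1)

  z <- eeg_segment(matrix(0, 2, 512), fs = 256, label = "interictal")
  expect_true(all(remove_line_noise(z, cfg)$samples == 0))
})

test_that("harmonic bands above Nyquist are skipped, fundamentals error", {
  cfg <- preprocess_config(line_freq = 60)
  s <- make_sine_segment(30, fs = 200, secs = 4)  # Nyquist 100 < 117 Hz
  expect_message(remove_line_noise(s, cfg), "skipping notch band")
  bad <- preprocess_config(line_freq = 60,
                           notch_bands = list(c(95, 130)))
  expect_error(remove_line_noise(make_sine_segment(10, fs = 200), bad),
               "Nyquist")
})

test_that("STFT window counts and peak bins match direct DFT arithmetic", {
  cfg60 <- preprocess_config(window_s = 60, overlap = 0)
  x <- stats::rnorm(600 * 4)             # 600 s at a light 4 Hz rate
  expect_equal(ncol(stft_channel(x, 4, cfg60)), 10L)

  cfg1 <- preprocess_config(window_s = 1, overlap = 0)
  expect_true(all(stft_channel(numeric(256 * 3), 256, cfg1) == 0))

  t <- (0:(256 * 4 - 1)) / 256
  m <- stft_channel(sin(2 * pi * 10 * t), 256, cfg1)
  expect_equal(dim(m), c(129L, 4L))
  for (j in 1:4) expect_equal(which.max(m[, j]), 10L + 1L)  # bin k <-> k Hz

  expect_error(stft_channel(numeric(100), 256, cfg1), "shorter than")
})

test_that("assembled images have contract shape and range", {
  cfg <- preprocess_config(window_s = 60, out_size = 256)
  mats <- replicate(16, matrix(stats::runif(128 * 10), 128, 10),
                    simplify = FALSE)
  img <- assemble_image(mats, cfg, label = "preictal")
  expect_equal(dim(img$pixels), c(256L, 256L, 3L))
  expect_gte(min(img$pixels), -1)
  expect_lte(max(img$pixels), 1)
  expect_identical(img$pixels[, , 1], img$pixels[, , 3])

  # constant input maps to the documented -1 convention
  const <- assemble_image(list(matrix(3, 32, 8)), preprocess_config(out_size = 16))
  expect_true(all(const$pixels == -1))

  bad <- list(matrix(1, 8, 4), matrix(1, 8, 5))
  expect_error(assemble_image(bad, cfg), "channel 2")
})

test_that("reversing channel order flips the stacked band structure", {
  cfg <- preprocess_config(out_size = 64, log_transform = FALSE)
  mats <- lapply(c(0.2, 0.4, 0.6, 0.8), function(v) matrix(v, 32, 8))
  fwd <- assemble_image(mats, cfg)
  rev_ <- assemble_image(rev(mats), cfg)
  # compare block medians: the reversed stacking is the vertical flip
  qmed <- function(img) vapply(0:3, function(q)
    stats::median(img$pixels[(q * 16 + 2):(q * 16 + 15), , 1]), 0)
  expect_equal(qmed(rev_), rev(qmed(fwd)), tolerance = 1e-6)
})

test_that("dataset preprocessing conserves labels and count", {
  imgs <- desk_images(6)
  expect_length(imgs, 12L)
  expect_equal(sum(label_of(imgs) == "preictal"), 6L)
  expect_true(all(vapply(imgs, function(im)
    all(dim(im$pixels) == c(64, 64, 3)), TRUE)))
  expect_true(all(vapply(imgs, function(im)
    min(im$pixels) >= -1 && max(im$pixels) <= 1, TRUE)))
  expect_identical(preprocess_dataset(list(), preprocess_config()), list())
})

test_that("per-segment failures are reported with the segment index", {
  cfg <- preprocess_config(window_s = 1, out_size = 16, line_freq = 60)
  good <- simulate_segment(sim_preset("desk", seed = 3), "preictal")
  short <- eeg_segment(matrix(stats::rnorm(2 * 100), 2), fs = 256,
                       label = "interictal")
  expect_error(preprocess_dataset(list(good, short), cfg, quiet = TRUE),
               "segment 2")
})
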