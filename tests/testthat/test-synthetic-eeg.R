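test_that("segment simulation is deterministic and shape-correct", {
  cfg <- sim_preset("desk", seed = 42)
  s1 <- simulate_segment(cfg, "preictal")
  s2 <- simulate_segment(cfg, "preictal")
  expect_identical(s1$samples, s2$samples)
  expect_equal(dim(s1$samples), c(8L, round(8 * 256)))
  expect_true(all(is.finite(s1$samples)))
  expect_error(simulate_segment(cfg, "ictal"), "interictal, preictal")
})

test_that("a source-free configuration yields an all-zero segment", {
  cfg <- sim_config(n_channels = 2, fs = 256, segment_len = 2,
                    preictal_bands = NULL, interictal_bands = NULL,
                    background_amp = 0, noise_sd = 0, line_noise_amp = 0)
  expect_true(all(simulate_segment(cfg, "preictal")$samples == 0))
})

test_that("line-noise-only segments peak at the mains frequency", {
  cfg <- sim_config(n_channels = 3, fs = 256, segment_len = 4,
                    preictal_bands = NULL, interictal_bands = NULL,
                    background_amp = 0, noise_sd = 0, line_noise_amp = 1,
                    line_noise_freq = 60, seed = 3)
  seg <- simulate_segment(cfg, "interictal")
  for (ch in 1:3) {
    sp <- stats::spec.pgram(seg$samples[ch, ], plot = FALSE, taper = 0,
                            fast = FALSE)
    expect_equal(sp$freq[which.max(sp$spec)] * cfg$fs, 60)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(fs = 40, preictal_bands = list(c(24, 4, 1))),
               "Nyquist")
  expect_error(sim_config(n_channels = 0), "n_channels")
  expect_error(sim_config(segment_len = 0), "segment_len")
})

test_that("datasets are balanced, ordered and reproducible", {
  cfg <- sim_preset("desk", seed = 5)
  ds <- simulate_dataset(cfg, 3)
  expect_length(ds, 6L)
  expect_equal(as.vector(table(label_of(ds))), c(3L, 3L))
  # fixed documented order: interictal/preictal pairs
  expect_equal(label_of(ds)[1:2], c("interictal", "preictal"))
  expect_equal(vapply(ds, function(s) s$t_start, 0),
               (0:5) * cfg$segment_len)
  ds2 <- simulate_dataset(cfg, 3)
  expect_identical(ds[[4]]$samples, ds2[[4]]$samples)
})

test_that("classes are linearly separable from band log-power features", {
  cfg <- sim_preset("desk", seed = 11)
  ds <- simulate_dataset(cfg, 50)
  band_power <- function(x, fs, lo, hi) {
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, fast = FALSE)
    f <- sp$freq * fs
    mean(sp$spec[f >= lo & f <= hi])
  }
  feats <- t(vapply(ds, function(s) {
    c(a = log(mean(apply(s$samples, 1, band_power, cfg$fs, 8, 12))),
      b = log(mean(apply(s$samples, 1, band_power, cfg$fs, 22, 26))))
  }, numeric(2)))
  y <- as.integer(label_of(ds) == "preictal")
  fit <- suppressWarnings(stats::glm(y ~ feats, family = stats::binomial))
  acc <- mean((stats::fitted(fit) > 0.5) == y)
  expect_gt(acc, 0.9)
})

test_that("each class dominates its own designated band (spectral contract)", {
  cfg <- sim_preset("desk", seed = 13)
  ds <- simulate_dataset(cfg, 16)   # 32 segments
  welch_power <- function(s, lo, hi) {
    mean(apply(s$samples, 1, function(x) {
      sp <- stats::spec.pgram(x, spans = 5, plot = FALSE, taper = 0,
                              fast = FALSE)
      f <- sp$freq * cfg$fs
      mean(sp$spec[f >= lo & f <= hi])
    }))
  }
  pre <- Filter(function(s) s$label == "preictal", ds)
  int <- Filter(function(s) s$label == "interictal", ds)
  # pre-ictal band: 24 +/- 2 Hz; interictal band: 10 +/- 1 Hz
  expect_gt(mean(vapply(pre, welch_power, 0, 22, 26)),
            mean(vapply(int, welch_power, 0, 22, 26)))
  expect_gt(mean(vapply(int, welch_power, 0, 9, 11)),
            mean(vapply(pre, welch_power, 0, 9, 11)))
})

test_that("timelines respect SPH, the 4-hour exclusion and feasibility", {
  cfg <- sim_preset("desk", seed = 21)
  tl0 <- simulate_timeline(cfg, duration_h = 6, n_seizures = 0)
  expect_length(tl0$seizure_onsets, 0L)
  expect_true(all(tl0$segment_index$label == "interictal"))

  tl <- simulate_timeline(cfg, duration_h = 10, n_seizures = 2,
                          sph_min = 10, sop_min = 30)
  expect_length(tl$seizure_onsets, 2L)
  expect_true(all(diff(tl$seizure_onsets) > 40 * 60))
  pre <- tl$segment_index[tl$segment_index$label == "preictal", ]
  # every pre-ictal segment ends at least one SPH before its onset
  for (t in pre$t_start) {
    gap <- tl$seizure_onsets - (t + cfg$segment_len)
    expect_true(any(gap >= 10 * 60))
  }
  int <- tl$segment_index[tl$segment_index$label == "interictal", ]
  for (t in int$t_start)
    expect_true(all(abs(tl$seizure_onsets - t) >= 4 * 3600))

  expect_error(simulate_timeline(cfg, duration_h = 1, n_seizures = 100),
               "cannot place")
})

test_that("EEG datasets survive a write/read round trip", {
  cfg <- sim_preset("desk", seed = 31, n_channels = 3, segment_len = 1)
  ds <- simulate_dataset(cfg, 2)
  dir <- withr::local_tempdir()
  write_eeg_dataset(ds, dir, config = cfg)
  back <- read_eeg_dataset(dir)
  expect_length(back, 4L)
  expect_identical(back[[2]]$samples, ds[[2]]$samples)
  expect_identical(label_of(back), label_of(ds))
  expect_equal(back[[3]]$t_start, ds[[3]]$t_start)
})
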