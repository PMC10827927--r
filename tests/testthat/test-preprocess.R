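# Filtering, resampling, segmentation, normalization and labelling.

test_that("band-pass attenuates out-of-band tones and passes in-band ones", {
  # 60 Hz tone outside a 1-50 Hz band at 200 Hz sampling
  rec60 <- make_sine_recording(freqs = 60, fs = 200, seconds = 10)
  out <- bandpass_filter(rec60, 1, 50)
  expect_lt(rms(out$signal[1, ]) / rms(rec60$signal[1, ]), 0.05)

  # 10 Hz tone inside a 4-45 Hz band passes nearly unchanged
  rec10 <- make_sine_recording(freqs = 10, fs = 200, seconds = 10)
  out10 <- bandpass_filter(rec10, 4, 45)
  expect_equal(rms(out10$signal[1, ]), rms(rec10$signal[1, ]),
               tolerance = 0.1)

  # DC is outside any band-pass
  dc <- eeg_recording(matrix(1, 1, 2000), 200, "CH1")
  outdc <- bandpass_filter(dc, 4, 45)
  expect_lt(rms(outdc$signal[1, ]), 0.02)

  expect_error(bandpass_filter(rec10, 4, 101), "Nyquist")
  expect_identical(ncol(out$signal), 2000L)
})

test_that("notch removes 50 Hz but leaves 20 Hz intact", {
  rec50 <- make_sine_recording(freqs = 50, fs = 200, seconds = 10)
  out <- notch_filter(rec50, 50)
  expect_lt(rms(out$signal[1, ]) / rms(rec50$signal[1, ]), 0.10)

  rec20 <- make_sine_recording(freqs = 20, fs = 200, seconds = 10)
  out20 <- notch_filter(rec20, 50)
  expect_equal(rms(out20$signal[1, ]), rms(rec20$signal[1, ]),
               tolerance = 0.05)

  zero <- eeg_recording(matrix(0, 1, 2000), 200, "CH1")
  expect_equal(max(abs(notch_filter(zero, 50)$signal)), 0)
  expect_error(notch_filter(rec20, 120), "Nyquist")
})

test_that("filters are linear operators", {
  set.seed(7)
  fs <- 200
  x <- matrix(stats::rnorm(2000), 1)
  y <- matrix(stats::rnorm(2000), 1)
  fx <- bandpass_filter(eeg_recording(x, fs, "A"), 4, 45)$signal
  fy <- bandpass_filter(eeg_recording(y, fs, "A"), 4, 45)$signal
  fxy <- bandpass_filter(eeg_recording(2 * x + 3 * y, fs, "A"), 4, 45)$signal
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-8)
})

test_that("resampling adjusts length and preserves spectral peaks", {
  rec <- make_sine_recording(freqs = 5, fs = 1000, seconds = 1)
  out <- resample_recording(rec, 128)
  expect_identical(ncol(out$signal), 128L)
  expect_equal(out$sampling_rate, 128)

  # identity when target equals source (bit-equal)
  expect_identical(resample_recording(rec, 1000)$signal, rec$signal)

  # 5 Hz peak survives 1000 -> 200 Hz
  rec10s <- make_sine_recording(freqs = 5, fs = 1000, seconds = 10)
  down <- resample_recording(rec10s, 200)
  n <- ncol(down$signal)
  sp <- Mod(stats::fft(down$signal[1, ]))[2:(n %/% 2)]
  peak_hz <- which.max(sp) * 200 / n
  expect_equal(peak_hz, 5, tolerance = 0.2)
})

test_that("segmentation counts windows conservatively", {
  rec60 <- make_sine_recording(fs = 128, seconds = 60)
  ep <- segment_epochs(rec60, 4)
  expect_identical(n_epochs(ep), 15L)
  expect_identical(dim(ep$epochs)[3], 512L)

  rec63 <- make_sine_recording(fs = 128, seconds = 63)
  expect_identical(n_epochs(segment_epochs(rec63, 4)), 15L)

  rec3 <- make_sine_recording(fs = 128, seconds = 3)
  expect_warning(ep0 <- segment_epochs(rec3, 4), "shorter")
  expect_identical(n_epochs(ep0), 0L)

  # conservation: no samples invented
  expect_lte(n_epochs(ep) * dim(ep$epochs)[3], ncol(rec60$signal))
  # epochs inherit the subject
  expect_identical(unique(ep$subject_ids), "s01")
})

test_that("overlapping segmentation advances by epoch minus overlap", {
  rec <- make_sine_recording(fs = 100, seconds = 10)
  ep <- segment_epochs(rec, epoch_seconds = 2, overlap = 1)
  expect_identical(n_epochs(ep), 9L)
})

test_that("per-channel per-epoch z-scoring is exact, safe and idempotent", {
  set.seed(3)
  ep <- tiny_task(n_per_class = 4)
  ep$epochs[1, 2, ] <- 7                          # constant trace
  nm <- normalize_epochs(ep)
  expect_equal(mean(nm$epochs[2, 1, ]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(nm$epochs[2, 1, ]), 1, tolerance = 1e-9)
  expect_equal(max(abs(nm$epochs[1, 2, ])), 0)
  nm2 <- normalize_epochs(nm)
  expect_equal(nm2$epochs, nm$epochs, tolerance = 1e-6)
})

test_that("quadrant labelling follows the >= threshold tie rule", {
  df <- data.frame(valence = c(7, 5, 2, 2, 6), arousal = c(8, 5, 8, 2, 3))
  lab <- assign_labels(df, label_scheme("quadrant4"))
  expect_identical(lab$label_names, c("HAHV", "LAHV", "HALV", "LALV"))
  expect_identical(lab$labels, c(0L, 0L, 2L, 3L, 1L))

  expect_error(assign_labels(data.frame(valence = 0, arousal = 5),
                             label_scheme("quadrant4")), "\\[1, 9\\]")

  bv <- assign_labels(df, label_scheme("binary_valence"))
  expect_identical(bv$labels, c(1L, 1L, 0L, 0L, 1L))

  dis <- assign_labels(c("sad", "happy", "sad"), label_scheme("discrete"))
  expect_identical(sort(dis$label_names), c("happy", "sad"))
  expect_true(all(dis$labels %in% 0:1))
})

test_that("preset pipelines run end to end and produce finite epochs", {
  set.seed(5)
  sig <- matrix(stats::rnorm(2 * 2560, sd = 10), 2)
  rec <- eeg_recording(sig, 256, c("C3", "C4"))
  dp <- apply_pipeline(rec, pipeline_preset("deap"))
  expect_s3_class(dp, "epoch_set")
  expect_equal(dp$sampling_rate, 128)
  expect_identical(dim(dp$epochs)[3], 512L)
  expect_true(all(is.finite(dp$epochs)))

  sv <- apply_pipeline(rec, pipeline_preset("seedv"))
  expect_equal(sv$sampling_rate, 200)
  expect_identical(dim(sv$epochs)[3], 800L)
  expect_true(all(is.finite(sv$epochs)))
  # normalized output: unit variance per trace
  expect_equal(stats::sd(sv$epochs[1, 1, ]), 1, tolerance = 1e-6)

  expect_identical(apply_pipeline(rec, list())$signal, rec$signal)
  expect_error(apply_pipeline(rec, list(list(step = "sparkle"))), "unknown")
})
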