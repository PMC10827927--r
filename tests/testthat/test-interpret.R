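# Interpretability: kernel spectra, topographies, ablation, Gaussian fits.

test_that("frequency response finds a windowed cosine's band", {
  fs <- 128
  tt <- 0:63 / fs
  k20 <- cos(2 * pi * 20 * tt) * signal::hamming(64)
  sp <- kernel_frequency_response(k20, fs)
  expect_equal(sp$dominant_frequency, 20, tolerance = 0.5)
  expect_identical(sp$band_label, "beta")
  expect_true(all(sp$magnitude >= 0))
  expect_equal(max(sp$frequency), fs / 2)

  # delta impulse: flat spectrum, broadband
  imp <- c(1, rep(0, 31))
  spi <- kernel_frequency_response(imp, fs)
  expect_gt(spi$flatness, 0.99)
  expect_identical(spi$band_label, "broadband")

  # discrete Gaussian: monotone low-pass, dominant at the grid floor
  g <- exp(-((0:63) - 31.5)^2 / (2 * 8^2))
  spg <- kernel_frequency_response(g, fs)
  expect_lt(spg$dominant_frequency, 2)
  expect_true(all(diff(spg$magnitude[spg$frequency < 6]) < 1e-6))
  expect_true(spg$band_label %in% c("delta", "broadband"))

  expect_warning(spz <- kernel_frequency_response(rep(0, 16), fs), "zero")
  expect_identical(spz$band_label, "broadband")
  expect_true(is.na(spz$dominant_frequency))
})

test_that("kernel spectrum agrees with filtered-noise periodogram peak", {
  set.seed(41)
  fs <- 128
  tt <- 0:31 / fs
  k <- cos(2 * pi * 17 * tt) * signal::hamming(32)
  sp <- kernel_frequency_response(k, fs)
  # push long white noise through the kernel, find the periodogram peak
  x <- stats::rnorm(2^14)
  y <- stats::filter(x, k, method = "convolution", sides = 2)
  y <- y[!is.na(y)]
  n <- length(y)
  pg <- Mod(stats::fft(y))[2:(n %/% 2)]^2
  fr <- (1:(n %/% 2 - 1)) * fs / n
  sm <- stats::filter(pg, rep(1 / 33, 33), sides = 2)
  peak <- fr[which.max(sm)]
  expect_equal(sp$dominant_frequency, peak, tolerance = fs / 2 / 512 + 0.5)
})

test_that("topomaps expose the stored spatial weights", {
  m <- build_ertnet(ertnet_config(32, 256, 2, F1 = 4, T = 16, D = 3,
                                  n_heads = 2), seed = 43)
  maps <- spatial_topomap(m, 2, "deap32")
  expect_length(maps, 3)
  for (d in 1:3) {
    expect_identical(unname(maps[[d]]$weights), m$params$Ws[, d, 2])
    expect_identical(names(maps[[d]]$weights), get_montage("deap32")$channel)
  }
  expect_error(spatial_topomap(m, 9, "deap32"), "1..4")
  expect_error(spatial_topomap(m, 1, "seedv62"), "channel count")
})

test_that("montage resources provide on-disc coordinates", {
  for (mn in c("deap32", "seedv62")) {
    mt <- get_montage(mn)
    expect_identical(nrow(mt), if (mn == "deap32") 32L else 62L)
    expect_false(any(is.na(mt$x)))
    expect_true(all(mt$x^2 + mt$y^2 <= 1 + 1e-9))
  }
  # left/right symmetry: T7 mirrors T8
  d <- get_montage("deap32")
  expect_equal(d$x[d$channel == "T7"], -d$x[d$channel == "T8"])
  expect_lt(d$x[d$channel == "T7"], -0.8)
})

test_that("ablation silences branches, restores weights, and hits the
          chance floor when everything is removed", {
  ep <- tiny_task(n_per_class = 25, amplitude = 4)
  m <- fit(build_ertnet(tiny_config(), seed = 47), ep, quick_tc())$model
  base <- evaluate(m, ep)
  before <- predict(m, ep)

  none <- ablate(m, integer(0), ep)
  expect_identical(none$removed, "None")
  expect_identical(none$auc_average, base$auc_macro)

  one <- ablate(m, 1, ep)
  expect_true(is.finite(one$auc_average))
  # weight-restoring: the model is untouched by ablation calls
  expect_identical(predict(m, ep), before)

  # ablating all temporal kernels leaves constant logits: AUC 0.5 per class
  all_out <- ablate(m, seq_len(m$config$F1), ep)
  expect_equal(unname(all_out$per_class_auc), c(0.5, 0.5))
  probs <- predict(ertnet:::.ablate_params(m, seq_len(m$config$F1)), ep)
  expect_lt(max(apply(probs, 2, stats::sd)), 1e-10)
})

test_that("ablation study has the expected table layout and round-trips
          through CSV", {
  ep <- tiny_task(n_per_class = 25, amplitude = 4)
  m <- fit(build_ertnet(tiny_config(), seed = 53), ep, quick_tc())$model
  sets <- c(as.list(1:2), list(c(1, 2)))
  tab <- ablation_study(m, sets, ep)
  expect_identical(nrow(tab), 4L)                  # 2 singletons + 1 group + None
  expect_identical(tab$removed[4], "None")
  expect_true(all(tab$auc_average >= 0 & tab$auc_average <= 1))
  # singleton ablation cannot beat the unablated model by much
  expect_true(all(tab$auc_average[1:2] <= tab$auc_average[4] + 0.02))

  path <- file.path(withr::local_tempdir(), "ablation.csv")
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$auc_average, tab$auc_average, tolerance = 1e-12)
  expect_identical(back$removed, tab$removed)
})

test_that("gaussian fit recovers a planted sigma = 14 and rejects a cosine", {
  tt <- 1:101
  g <- 0.12 * exp(-(tt - 51)^2 / (2 * 14^2))
  f <- gaussian_fit(g)
  expect_equal(f$sigma, 14, tolerance = 0.1)
  expect_gt(f$r, 0.999)
  expect_equal(f$amplitude, 0.12, tolerance = 1e-6)
  expect_equal(f$amplitude_reduction, 1 / 0.12, tolerance = 1e-4)

  # scaling the kernel scales the amplitude, not sigma
  f2 <- gaussian_fit(3 * g)
  expect_equal(f2$amplitude, 0.36, tolerance = 1e-6)
  expect_equal(f2$sigma, 14, tolerance = 0.1)

  cosk <- cos(2 * pi * 20 * (0:63) / 128)
  fc <- gaussian_fit(cosk)
  expect_true(is.na(fc$r) || fc$r < 0.5)
})

test_that("kernel report bundles spectra, fits and topomaps per kernel", {
  m <- build_ertnet(ertnet_config(32, 256, 2, F1 = 8, T = 32, D = 4,
                                  n_heads = 2), seed = 59)
  rep <- kernel_report(m, 128, "deap32")
  expect_length(rep$kernels, 8)
  expect_identical(sum(vapply(rep$kernels, function(k) length(k$topomaps), 0L)),
                   32L)
  expect_identical(nrow(rep$summary), 8L)
  js <- kernel_report_json(rep)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(length(parsed$kernels$kernel_index), 8L)
  expect_true(all(c("summary", "sampling_rate") %in% names(parsed)))
})
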