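# Interpretability: temporal-kernel frequency responses with canonical EEG
# band labels, spatial topographies, retraining-free kernel ablation, and
# Gaussian-kernel similarity fits.

.band_edges <- list(delta = c(0, 4), theta = c(4, 8), alpha = c(8, 13),
                    beta = c(13, 30), gamma = c(30, 50))

.band_of <- function(freq) {
  for (nm in names(.band_edges)) {
    e <- .band_edges[[nm]]
    if (freq >= e[1] && freq < e[2]) return(nm)
  }
  "broadband"
}

#' Frequency response of a temporal kernel
#'
#' Magnitude of the discrete-time Fourier transform on a dense grid up to
#' Nyquist.  The dominant frequency is the argmax above 0.5 Hz; the band
#' label uses the canonical EEG edges (delta < 4, theta 4-8, alpha 8-13,
#' beta 13-30, gamma 30-50 Hz), with `"broadband"` when the spectral
#' flatness of the magnitude-squared response exceeds 0.5 (or above
#' 50 Hz).
#'
#' @param kernel Numeric kernel weight vector (length >= 2).
#' @param sampling_rate Hz.
#' @param n_grid Grid points on (0, Nyquist] (default 512).
#' @return An object of class `kernel_spectrum` with fields `frequency`,
#'   `magnitude`, `dominant_frequency`, `band_label`, `flatness`.
#' @export
kernel_frequency_response <- function(kernel, sampling_rate, n_grid = 512L) {
  assert_that(length(kernel) >= 2, "kernel must have length >= 2")
  assert_that(n_grid >= 512L, "n_grid must be >= 512")
  nyq <- sampling_rate / 2
  freq <- seq_len(n_grid) / n_grid * nyq
  tt <- seq_along(kernel) - 1
  # DTFT on the grid: H(f) = sum_t w[t] exp(-i 2 pi f t / Sr)
  E <- exp(-2i * pi * outer(freq / sampling_rate, tt))
  mag <- abs(as.vector(E %*% kernel))
  if (all(mag < 1e-14)) {
    warning("zero kernel: dominant frequency undefined; labeled broadband")
    return(structure(list(frequency = freq, magnitude = mag,
                          dominant_frequency = NA_real_,
                          band_label = "broadband", flatness = 1),
                     class = "kernel_spectrum"))
  }
  pow <- mag^2
  flat <- exp(mean(log(pow + 1e-300))) / mean(pow)
  sel <- freq > 0.5
  dom <- freq[sel][which.max(mag[sel])]
  band <- if (flat > 0.5) "broadband" else .band_of(dom)
  structure(list(frequency = freq, magnitude = mag,
                 dominant_frequency = dom, band_label = band,
                 flatness = flat),
            class = "kernel_spectrum")
}

#' Spatial topographies of one temporal kernel
#'
#' Extracts the D depthwise spatial weight vectors attached to the given
#' temporal kernel, paired with 2-D montage coordinates for numeric
#' topography reports.
#'
#' @param model An `ertnet_model`.
#' @param kernel_index Temporal kernel index in `1..F1`.
#' @param montage Montage name or channel vector understood by
#'   [get_montage()]; must match the model's channel count.
#' @return A list of D `topo_map` objects, each with `kernel_index`,
#'   `depth`, `weights` (named per channel) and `coordinates`.
#' @export
spatial_topomap <- function(model, kernel_index, montage) {
  cf <- model$config
  assert_that(kernel_index >= 1 && kernel_index <= cf$F1,
              sprintf("kernel_index must be in 1..%d", cf$F1))
  coords <- get_montage(montage)
  assert_that(nrow(coords) == cf$n_channels,
              "montage channel count must match the model")
  lapply(seq_len(cf$D), function(d) {
    w <- model$params$Ws[, d, kernel_index]
    names(w) <- coords$channel
    structure(list(kernel_index = kernel_index, depth = d, weights = w,
                   coordinates = coords),
              class = "topo_map")
  })
}

# Silence a set of temporal kernels: weights zeroed and the first-stage
# batch-norm affine neutralised so the branch contributes exactly zero
# after the first normalisation.  Returns a modified copy; the original
# model is untouched (R copy semantics make ablation weight-restoring).
.ablate_params <- function(model, kernels) {
  for (k in kernels) {
    model$params$Wt[, k] <- 0
    model$params$bn1$gamma[k] <- 0
    model$params$bn1$beta[k] <- 0
  }
  model
}

#' Evaluate the model with a set of temporal kernels removed
#'
#' "Removing" a kernel zeroes its temporal weights and the matching
#' first-stage batch-norm scale/shift, so the branch is exactly silent; the
#' model is then re-evaluated without retraining.  The input model is not
#' modified.
#'
#' @param model A trained `ertnet_model`.
#' @param kernels Integer vector of temporal kernel indices (possibly
#'   empty: the unablated reference evaluation).
#' @param test_ep Evaluation [epoch_set()].
#' @return One ablation-table row: list with `removed` (label),
#'   `auc_average`, `per_class_auc`, `accuracy`.
#' @export
ablate <- function(model, kernels, test_ep) {
  kernels <- as.integer(kernels)
  assert_that(all(kernels >= 1 & kernels <= model$config$F1),
              "kernel indices out of range")
  m <- if (length(kernels) > 0) .ablate_params(model, kernels) else model
  r <- evaluate(m, test_ep)
  list(removed = if (length(kernels) == 0) "None"
       else paste(sort(kernels), collapse = ", "),
       auc_average = r$auc_macro, per_class_auc = r$per_class_auc,
       accuracy = r$accuracy)
}

#' Kernel ablation study
#'
#' One row per removed kernel set (singletons and/or named groups) plus the
#' `"None"` reference row, mirroring the usual ablation-table layout
#' (average AUC and per-class AUC per row).  The average column is the
#' row-wise mean of the per-class AUCs.
#'
#' @param model A trained `ertnet_model`.
#' @param sets List of integer vectors (kernel sets to remove).
#' @param test_ep Evaluation [epoch_set()].
#' @return A data frame: `removed`, `auc_average`, one `auc_<class>`
#'   column per class, `accuracy`.
#' @export
ablation_study <- function(model, sets, test_ep) {
  rows <- c(lapply(sets, function(s) ablate(model, s, test_ep)),
            list(ablate(model, integer(0), test_ep)))
  out <- do.call(rbind, lapply(rows, function(r) {
    df <- data.frame(removed = r$removed, auc_average = r$auc_average,
                     accuracy = r$accuracy)
    for (nm in names(r$per_class_auc)) {
      df[[paste0("auc_", nm)]] <- r$per_class_auc[[nm]]
    }
    df
  }))
  rownames(out) <- NULL
  out
}

#' Gaussian similarity fit of a temporal kernel
#'
#' Bounded nonlinear least squares of `a * exp(-(t - t0)^2 / (2 sigma^2))`
#' against the kernel weights; `t0` starts at the kernel's centre of
#' (absolute) mass and `sigma` at T/6.  Reports the fitted width `sigma`
#' (samples), the peak amplitude `a`, the magnitude reduction relative to
#' a unit-peak Gaussian (`1/|a|`), and the Pearson correlation `r` between
#' kernel and fit.  Non-convergence is reported with `r = NA`.
#'
#' @param kernel Numeric kernel weights (length >= 5).
#' @return An object of class `gaussian_fit` with `sigma`, `amplitude`,
#'   `amplitude_reduction`, `t0`, `r`.
#' @export
gaussian_fit <- function(kernel) {
  assert_that(length(kernel) >= 5, "kernel must have length >= 5")
  tt <- seq_along(kernel)
  w <- abs(kernel) + 1e-12
  start <- list(a = kernel[which.max(abs(kernel))],
                t0 = sum(tt * w) / sum(w),
                sigma = length(kernel) / 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(tt - t0)^2 / (2 * sigma^2)),
                      data = data.frame(tt = tt, y = kernel),
                      start = start,
                      lower = c(a = -Inf, t0 = min(tt) - length(tt),
                                sigma = 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(sigma = NA_real_, amplitude = NA_real_,
                          amplitude_reduction = NA_real_, t0 = NA_real_,
                          r = NA_real_),
                     class = "gaussian_fit"))
  }
  cf <- stats::coef(fit)
  fitted_curve <- stats::fitted(fit)
  r <- if (stats::sd(fitted_curve) < 1e-12) 0 else
    stats::cor(kernel, fitted_curve)
  structure(list(sigma = unname(abs(cf["sigma"])),
                 amplitude = unname(cf["a"]),
                 amplitude_reduction = 1 / abs(unname(cf["a"])),
                 t0 = unname(cf["t0"]), r = r),
            class = "gaussian_fit")
}

#' Full kernel report
#'
#' Per temporal kernel: frequency spectrum with band label, Gaussian
#' similarity fit, and the D spatial topographies; plus a summary of which
#' kernels are band-selective and which are Gaussian-like (low-pass
#' smoothing kernels the model shapes to suppress high-frequency noise).
#'
#' @param model A trained `ertnet_model`.
#' @param sampling_rate Hz of the training data.
#' @param montage Montage name or channel vector matching the model.
#' @param gaussian_r_threshold Pearson r above which a kernel counts as
#'   Gaussian-like (default 0.9).
#' @return An object of class `kernel_report`: list `kernels` (per-kernel
#'   bundles) and `summary` (band labels, dominant frequencies, flags).
#' @export
kernel_report <- function(model, sampling_rate, montage,
                          gaussian_r_threshold = 0.9) {
  cf <- model$config
  kernels <- lapply(seq_len(cf$F1), function(f) {
    w <- model$params$Wt[, f]
    sp <- kernel_frequency_response(w, sampling_rate)
    gf <- gaussian_fit(w)
    list(kernel_index = f, weights = w, spectrum = sp, gaussian = gf,
         topomaps = spatial_topomap(model, f, montage))
  })
  summary <- data.frame(
    kernel = seq_len(cf$F1),
    dominant_frequency = vapply(kernels, function(k)
      k$spectrum$dominant_frequency, 0),
    band = vapply(kernels, function(k) k$spectrum$band_label, ""),
    flatness = vapply(kernels, function(k) k$spectrum$flatness, 0),
    gaussian_r = vapply(kernels, function(k) k$gaussian$r, 0))
  summary$band_selective <- summary$band != "broadband"
  summary$gaussian_like <- !is.na(summary$gaussian_r) &
    summary$gaussian_r > gaussian_r_threshold
  structure(list(kernels = kernels, summary = summary,
                 sampling_rate = sampling_rate),
            class = "kernel_report")
}

#' Serialise a kernel report to JSON
#'
#' @param report A [kernel_report()].
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
kernel_report_json <- function(report, path = NULL) {
  obj <- list(
    sampling_rate = report$sampling_rate,
    summary = report$summary,
    kernels = lapply(report$kernels, function(k) list(
      kernel_index = k$kernel_index,
      weights = k$weights,
      dominant_frequency = k$spectrum$dominant_frequency,
      band_label = k$spectrum$band_label,
      flatness = k$spectrum$flatness,
      gaussian = unclass(k$gaussian),
      topomaps = lapply(k$topomaps, function(tm)
        list(depth = tm$depth, weights = as.list(tm$weights))))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
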