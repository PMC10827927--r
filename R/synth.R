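# Synthetic EEG with controllable class structure: band- and
# channel-localised oscillatory signatures embedded in 1/f background noise,
# optionally with 50 Hz line interference and broadband high-frequency
# bursts.  The generator exists so that the classifier and all of its
# interpretability procedures can be validated against a known ground truth.

#' Pink (1/f^a) noise by spectral synthesis
#'
#' Draws random spectral phases with amplitude proportional to
#' `f^(-exponent/2)` (so power falls as `1/f^exponent`), inverts the
#' spectrum, and standardises the trace to zero mean and unit variance.
#' `exponent = 0` gives white noise.
#'
#' @param n_samples Trace length (>= 2).
#' @param exponent Spectral exponent `a` in `1/f^a` (default 1).
#' @return A numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, exponent = 1) {
  assert_that(n_samples >= 2, "need at least 2 samples")
  n <- n_samples
  nh <- (n - 1L) %/% 2L                     # strictly positive, non-Nyquist bins
  spec <- complex(real = numeric(n), imaginary = numeric(n))
  if (nh >= 1) {
    amp <- (seq_len(nh))^(-exponent / 2)
    phase <- stats::runif(nh, 0, 2 * pi)
    spec[1L + seq_len(nh)] <- amp * exp(1i * phase)
    spec[n + 1L - seq_len(nh)] <- Conj(spec[1L + seq_len(nh)])
  }
  if (n %% 2L == 0L) {                      # real-valued Nyquist bin
    spec[n / 2L + 1L] <- (n / 2)^(-exponent / 2) * sample(c(-1, 1), 1L)
  }
  x <- Re(stats::fft(spec, inverse = TRUE))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

#' Class signature: a band- and channel-localised oscillation
#'
#' @param band Numeric length-2 vector `(low, high)` in Hz.
#' @param target_channels Channel labels that carry the oscillation.
#' @param amplitude Oscillation amplitude in microvolts.
#' @param phase_jitter Standard deviation (radians) of per-channel phase
#'   offsets around the epoch's common phase.
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(band, target_channels, amplitude = 2,
                            phase_jitter = 0) {
  assert_that(length(band) == 2 && band[1] > 0 && band[2] > band[1],
              "band must be (low, high) with 0 < low < high")
  structure(list(band = as.numeric(band),
                 target_channels = as.character(target_channels),
                 amplitude = amplitude, phase_jitter = phase_jitter),
            class = "class_signature")
}

#' Synthetic-EEG generator configuration
#'
#' Defaults emulate the dimensional-dataset geometry (32 channels at
#' 128 Hz, 4-s epochs).  Background noise defaults to pink noise with
#' exponent 1 plus a little white noise; line interference and
#' high-frequency artifacts are off by default so that the preprocessing
#' filters can be exercised separately.
#'
#' @param montage `"deap32"`, `"seedv62"`, or a character vector of channel
#'   labels.
#' @param sampling_rate Hz.
#' @param epoch_seconds Epoch duration, seconds.
#' @param n_subjects Number of simulated subjects.
#' @param epochs_per_subject_per_class Epochs generated per subject and
#'   class.
#' @param signatures Named list mapping class name to [class_signature()];
#'   a class with a `NULL` entry carries no oscillatory signature.
#' @param noise List with `pink_exponent`, `pink_sd`, `white_sd`,
#'   `line_50hz_amp`, `hf_artifact_amp`.
#' @param seed Integer seed; identical seeds give bit-identical data.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(montage = "deap32", sampling_rate = 128,
                         epoch_seconds = 4, n_subjects = 4,
                         epochs_per_subject_per_class = 25,
                         signatures = list(
                           calm = NULL,
                           excited = class_signature(c(13, 30), c("T7", "T8"))),
                         noise = list(pink_exponent = 1, pink_sd = 1,
                                      white_sd = 0.5, line_50hz_amp = 0,
                                      hf_artifact_amp = 0),
                         seed = 1L) {
  assert_that(length(signatures) >= 2, "need at least 2 classes")
  channels <- get_montage(montage)$channel
  nyq <- sampling_rate / 2
  for (nm in names(signatures)) {
    sg <- signatures[[nm]]
    if (is.null(sg)) next
    assert_that(sg$band[2] < nyq,
                sprintf("signature band for class '%s' exceeds Nyquist %g Hz",
                        nm, nyq))
    missing <- setdiff(sg$target_channels, channels)
    assert_that(length(missing) == 0,
                sprintf("target channels not in montage: %s",
                        paste(missing, collapse = ", ")))
  }
  defaults <- list(pink_exponent = 1, pink_sd = 1, white_sd = 0.5,
                   line_50hz_amp = 0, hf_artifact_amp = 0)
  noise <- utils::modifyList(defaults, noise)
  structure(list(montage = montage, channels = channels,
                 sampling_rate = sampling_rate,
                 epoch_seconds = epoch_seconds, n_subjects = n_subjects,
                 epochs_per_subject_per_class = epochs_per_subject_per_class,
                 signatures = signatures, noise = noise,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a labelled synthetic epoch set
#'
#' Each epoch is pink noise plus white noise on every channel, optionally
#' plus a 50 Hz line component and broadband (>45 Hz) bursts, plus the
#' class's narrow-band oscillation on its target channels only.  The
#' oscillation's centre frequency is drawn uniformly within the class band
#' per epoch (so a correct model must learn a band-pass, not a single
#' tone) and its phase is random.
#'
#' @param config A [synth_config()].
#' @return A list with `epochs` (an [epoch_set()]) and `manifest` (the
#'   ground truth: per-class band, target channels and amplitude, plus the
#'   generator geometry).
#' @export
generate_synth <- function(config) {
  set.seed(config$seed)
  fs <- config$sampling_rate
  n_s <- round(config$epoch_seconds * fs)
  channels <- config$channels
  n_ch <- length(channels)
  classes <- names(config$signatures)
  per <- config$epochs_per_subject_per_class
  total <- config$n_subjects * length(classes) * per
  ep <- array(0, c(total, n_ch, n_s))
  labels <- integer(total)
  subjects <- character(total)
  tt <- (seq_len(n_s) - 1) / fs
  nz <- config$noise
  i <- 0L
  for (subj in seq_len(config$n_subjects)) {
    for (k in seq_along(classes)) {
      sg <- config$signatures[[k]]
      for (r in seq_len(per)) {
        i <- i + 1L
        x <- matrix(0, n_ch, n_s)
        for (c in seq_len(n_ch)) {
          if (nz$pink_sd > 0) {
            x[c, ] <- nz$pink_sd * pink_noise(n_s, nz$pink_exponent)
          }
          if (nz$white_sd > 0) {
            x[c, ] <- x[c, ] + stats::rnorm(n_s, sd = nz$white_sd)
          }
        }
        if (nz$line_50hz_amp > 0) {
          ph <- stats::runif(1, 0, 2 * pi)
          x <- x + matrix(nz$line_50hz_amp * sin(2 * pi * 50 * tt + ph),
                          n_ch, n_s, byrow = TRUE)
        }
        if (nz$hf_artifact_amp > 0) {
          # short broadband bursts above 45 Hz on random channels
          for (b in seq_len(2)) {
            ch <- sample.int(n_ch, 1L)
            at <- sample.int(n_s - 19L, 1L)
            burst <- stats::rnorm(20, sd = nz$hf_artifact_amp)
            hf <- burst * cos(2 * pi * (45 + 0.4 * (fs / 2 - 45)) *
                                tt[seq_len(20)])
            x[ch, at:(at + 19L)] <- x[ch, at:(at + 19L)] + hf
          }
        }
        if (!is.null(sg)) {
          f0 <- stats::runif(1, sg$band[1], sg$band[2])
          ph0 <- stats::runif(1, 0, 2 * pi)
          tgt <- match(sg$target_channels, channels)
          for (c in tgt) {
            ph <- ph0 + if (sg$phase_jitter > 0)
              stats::rnorm(1, sd = sg$phase_jitter) else 0
            x[c, ] <- x[c, ] + sg$amplitude * sin(2 * pi * f0 * tt + ph)
          }
        }
        ep[i, , ] <- x
        labels[i] <- k - 1L
        subjects[i] <- sprintf("s%02d", subj)
      }
    }
  }
  manifest <- list(
    classes = lapply(config$signatures, function(sg) {
      if (is.null(sg)) list(band = NULL, target_channels = NULL, amplitude = 0)
      else list(band = sg$band, target_channels = sg$target_channels,
                amplitude = sg$amplitude)
    }),
    montage = if (is.character(config$montage) && length(config$montage) == 1)
      config$montage else "custom",
    channels = channels, sampling_rate = fs,
    epoch_seconds = config$epoch_seconds, n_subjects = config$n_subjects,
    epochs_per_subject_per_class = per, noise = nz, seed = config$seed)
  list(epochs = epoch_set(ep, labels, classes, subjects, fs, channels,
                          config$epoch_seconds),
       manifest = manifest)
}
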