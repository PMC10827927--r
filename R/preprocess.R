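# Preprocessing: zero-phase FIR filtering, FFT resampling, segmentation,
# normalization and label assignment.

# Linear-phase FIR length for a Hamming window giving the requested
# transition width (Hz); forced odd, capped so reflection padding fits the
# signal.
.fir_length <- function(fs, n_samples, transition_hz = 0.5) {
  L <- ceiling(3.3 * fs / transition_hz)
  if (L %% 2 == 0) L <- L + 1
  cap <- 2L * (n_samples - 1L) + 1L
  if (L > cap) {
    L <- if (cap %% 2 == 0) cap - 1L else cap
    warning(sprintf("short signal: FIR length reduced to %d taps", L))
  }
  max(L, 3L)
}

# Zero-phase application of a symmetric odd-length FIR: reflect-pad each
# channel, apply the centred convolution, trim back to the original span.
.apply_fir <- function(signal, coef) {
  L <- length(coef)
  half <- (L - 1L) %/% 2L
  t(apply(signal, 1L, function(x) {
    n <- length(x)
    xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])  # even reflection
    y <- stats::filter(xp, coef, method = "convolution", sides = 2L)
    as.numeric(y[(half + 1L):(half + n)])
  }))
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR, applied without phase delay by
#' centred convolution after reflection padding; the output has the same
#' length as the input.  The filter order targets a 0.5 Hz transition band
#' at the recording's sampling rate.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Pass-band edges in Hz, `0 < low < high < ` Nyquist.
#' @param transition_hz Transition-band width in Hz (default 0.5).
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, low, high, transition_hz = 0.5) {
  nyq <- rec$sampling_rate / 2
  assert_that(low > 0 && high > low, "need 0 < low < high")
  assert_that(high < nyq,
              sprintf("high edge %g Hz must be below Nyquist %g Hz", high, nyq))
  L <- .fir_length(rec$sampling_rate, ncol(rec$signal), transition_hz)
  coef <- signal::fir1(L - 1L, c(low, high) / nyq, type = "pass")
  rec$signal <- .apply_fir(rec$signal, coef)
  rec
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Removes narrow-band interference (by default 50 Hz mains) with a
#' windowed-sinc band-stop filter while preserving the rest of the spectrum.
#'
#' @param rec An [eeg_recording()].
#' @param freq Centre frequency to suppress, Hz (default 50).
#' @param width Half-width of the stop band in Hz (default 2).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, width = 2) {
  nyq <- rec$sampling_rate / 2
  assert_that(freq > 0 && freq < nyq,
              sprintf("notch frequency %g Hz must be below Nyquist %g Hz",
                      freq, nyq))
  edges <- c(max(freq - width, 0.1), min(freq + width, nyq * 0.999)) / nyq
  L <- .fir_length(rec$sampling_rate, ncol(rec$signal), transition_hz = 1)
  coef <- signal::fir1(L - 1L, edges, type = "stop")
  rec$signal <- .apply_fir(rec$signal, coef)
  rec
}

# Fourier-domain resampling of one trace to a new length, preserving
# amplitude; the new Nyquist bin is zeroed on downsampling.
.fft_resample_trace <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_new), imaginary = numeric(n_new))
  hm <- min(n, n_new) %/% 2
  Y[seq_len(hm)] <- X[seq_len(hm)]
  if (hm >= 2) Y[(n_new - hm + 2L):n_new] <- X[(n - hm + 2L):n]
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Resample a recording
#'
#' Fourier-domain resampling to `target_rate`; the new sample count is
#' `round(n * target_rate / sampling_rate)`.  When the target equals the
#' source rate the signal is returned untouched.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate New sampling rate in Hz.
#' @return The resampled recording with `sampling_rate` updated.
#' @export
resample_recording <- function(rec, target_rate) {
  assert_that(is.numeric(target_rate) && target_rate > 0,
              "target_rate must be positive")
  if (target_rate == rec$sampling_rate) return(rec)
  n_new <- round(ncol(rec$signal) * target_rate / rec$sampling_rate)
  rec$signal <- t(apply(rec$signal, 1L, .fft_resample_trace, n_new = n_new))
  if (n_new == 1L) rec$signal <- matrix(rec$signal, ncol = 1L)
  rec$sampling_rate <- as.numeric(target_rate)
  rec
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts half-open windows `[t, t + epoch_seconds)` starting at 0 and
#' advancing by `epoch_seconds - overlap`; the trailing remainder is
#' discarded.  Every epoch inherits the recording's subject and the given
#' class label.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_seconds Epoch duration, seconds (default 4).
#' @param overlap Overlap between consecutive epochs, seconds (default 0:
#'   non-repeating segments).
#' @param label Integer class code (0-based) applied to every epoch.
#' @param label_names Class name vector the code indexes into.
#' @return An [epoch_set()]; empty (with a warning) if the recording is
#'   shorter than one epoch.
#' @export
segment_epochs <- function(rec, epoch_seconds = 4, overlap = 0,
                           label = 0L, label_names = "unlabeled") {
  len <- round(epoch_seconds * rec$sampling_rate)
  assert_that(len >= 1, "epoch_seconds x sampling_rate must be >= 1")
  step <- len - round(overlap * rec$sampling_rate)
  assert_that(step >= 1, "overlap must be smaller than the epoch length")
  n <- ncol(rec$signal)
  starts <- seq.int(1L, by = step, length.out = max(0L, (n - len) %/% step + 1L))
  if (n < len) starts <- integer(0)
  if (length(starts) == 0L) {
    warning("recording shorter than one epoch; returning an empty epoch set")
    return(epoch_set(array(0, c(0L, nrow(rec$signal), len)), integer(0),
                     label_names, character(0), rec$sampling_rate,
                     rec$channel_names, epoch_seconds))
  }
  ep <- array(0, c(length(starts), nrow(rec$signal), len))
  for (i in seq_along(starts)) {
    ep[i, , ] <- rec$signal[, starts[i]:(starts[i] + len - 1L)]
  }
  epoch_set(ep, rep(as.integer(label), length(starts)), label_names,
            rep(rec$subject_id, length(starts)), rec$sampling_rate,
            rec$channel_names, epoch_seconds)
}

#' Combine epoch sets
#'
#' @param sets A list of [epoch_set()] objects sharing geometry, rate and
#'   label names.
#' @return One concatenated `epoch_set`.
#' @export
combine_epoch_sets <- function(sets) {
  assert_that(length(sets) >= 1, "need at least one epoch set")
  ref <- sets[[1]]
  for (s in sets) {
    assert_that(identical(dim(s$epochs)[-1], dim(ref$epochs)[-1]) &&
                  s$sampling_rate == ref$sampling_rate &&
                  identical(s$label_names, ref$label_names),
                "epoch sets must share geometry, rate and label names")
  }
  total <- sum(vapply(sets, n_epochs, 0L))
  ep <- array(0, c(total, dim(ref$epochs)[2], dim(ref$epochs)[3]))
  at <- 0L
  for (s in sets) {
    if (n_epochs(s) > 0) ep[(at + 1L):(at + n_epochs(s)), , ] <- s$epochs
    at <- at + n_epochs(s)
  }
  epoch_set(ep, unlist(lapply(sets, `[[`, "labels")), ref$label_names,
            unlist(lapply(sets, `[[`, "subject_ids")), ref$sampling_rate,
            ref$channel_names, ref$epoch_seconds)
}

#' Normalize epochs
#'
#' Z-scores every (epoch, channel) trace independently; constant traces map
#' to all zeros instead of dividing by zero.
#'
#' @param ep An [epoch_set()].
#' @param mode Only `"zscore_per_channel_per_epoch"` is defined.
#' @return The normalized `epoch_set`.
#' @export
normalize_epochs <- function(ep, mode = "zscore_per_channel_per_epoch") {
  mode <- match.arg(mode)
  assert_that(dim(ep$epochs)[3] >= 2, "need at least 2 samples per epoch")
  d <- dim(ep$epochs)
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      x <- ep$epochs[i, c, ]
      s <- stats::sd(x)
      ep$epochs[i, c, ] <- if (s < 1e-12) 0 else (x - mean(x)) / s
    }
  }
  ep
}

#' Label scheme for dimensional or discrete emotion labels
#'
#' @param mode `"quadrant4"` (four valence/arousal quadrants),
#'   `"binary_valence"`, `"binary_arousal"`, or `"discrete"` (labels passed
#'   through).
#' @param threshold Rating cut for the dimensional modes (default 5);
#'   ratings equal to the threshold count as "high".
#' @return An object of class `label_scheme`.
#' @export
label_scheme <- function(mode = c("quadrant4", "binary_valence",
                                  "binary_arousal", "discrete"),
                         threshold = 5) {
  structure(list(mode = match.arg(mode), threshold = threshold),
            class = "label_scheme")
}

#' Assign class labels from ratings or discrete labels
#'
#' Dimensional modes threshold 1-9 valence/arousal ratings; the quadrant
#' scheme yields the four classes HAHV, LAHV, HALV, LALV (high/low arousal
#' crossed with high/low valence), with ratings at the threshold counting as
#' high.
#'
#' @param ratings_or_labels For dimensional modes, a data frame with
#'   `valence` and `arousal` columns; for `"discrete"`, any vector of
#'   labels.
#' @param scheme A [label_scheme()].
#' @return A list with `labels` (0-based integer codes) and `label_names`.
#' @export
assign_labels <- function(ratings_or_labels, scheme = label_scheme()) {
  if (scheme$mode == "discrete") {
    f <- factor(ratings_or_labels)
    return(list(labels = as.integer(f) - 1L, label_names = levels(f)))
  }
  v <- ratings_or_labels$valence
  a <- ratings_or_labels$arousal
  assert_that(!is.null(v) && !is.null(a),
              "dimensional modes need valence and arousal columns")
  assert_that(all(v >= 1 & v <= 9) && all(a >= 1 & a <= 9),
              "ratings must lie in [1, 9]")
  th <- scheme$threshold
  switch(scheme$mode,
    quadrant4 = {
      names4 <- c("HAHV", "LAHV", "HALV", "LALV")
      code <- ifelse(v >= th & a >= th, 0L,
              ifelse(v >= th & a < th, 1L,
              ifelse(v < th & a >= th, 2L, 3L)))
      list(labels = code, label_names = names4)
    },
    binary_valence = list(labels = as.integer(v >= th),
                          label_names = c("LowValence", "HighValence")),
    binary_arousal = list(labels = as.integer(a >= th),
                          label_names = c("LowArousal", "HighArousal")))
}

#' Named preprocessing pipelines
#'
#' A pipeline is an ordered list of steps, each a list with a `step` name
#' (`bandpass`, `notch`, `resample`, `segment`, `normalize`) and its
#' arguments.  Two presets mirror common dataset conventions: `"deap"`
#' (band-pass 4-45 Hz, resample to 128 Hz, 4-s segments) and `"seedv"`
#' (notch 50 Hz, band-pass 1-50 Hz, 4-s segments, resample implied before
#' segmentation to 200 Hz, per-channel z-scoring).
#'
#' @param name `"deap"` or `"seedv"`.
#' @return A list of step specifications.
#' @export
pipeline_preset <- function(name = c("deap", "seedv")) {
  switch(match.arg(name),
    deap = list(list(step = "bandpass", low = 4, high = 45),
                list(step = "resample", target_rate = 128),
                list(step = "segment", epoch_seconds = 4)),
    seedv = list(list(step = "notch", freq = 50),
                 list(step = "bandpass", low = 1, high = 50),
                 list(step = "segment", epoch_seconds = 4),
                 list(step = "resample", target_rate = 200),
                 list(step = "normalize")))
}

#' Resample every epoch in an epoch set
#'
#' @param ep An [epoch_set()].
#' @param target_rate New sampling rate in Hz.
#' @return The resampled `epoch_set` with `sampling_rate` updated.
#' @export
resample_epochs <- function(ep, target_rate) {
  assert_that(target_rate > 0, "target_rate must be positive")
  if (target_rate == ep$sampling_rate) return(ep)
  d <- dim(ep$epochs)
  n_new <- round(d[3] * target_rate / ep$sampling_rate)
  out <- array(0, c(d[1], d[2], n_new))
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      out[i, c, ] <- .fft_resample_trace(ep$epochs[i, c, ], n_new)
    }
  }
  epoch_set(out, ep$labels, ep$label_names, ep$subject_ids, target_rate,
            ep$channel_names, n_new / target_rate)
}

#' Apply a preprocessing pipeline
#'
#' Steps acting on recordings (`bandpass`, `notch`) must precede `segment`;
#' `resample` works on either a recording or an epoch set; `normalize` acts
#' on segmented epochs.  An empty pipeline returns the input unchanged.
#'
#' @param x An [eeg_recording()] (or an [epoch_set()] if only epoch-level
#'   steps remain).
#' @param steps A list of step specifications (see [pipeline_preset()]).
#' @param label,label_names Passed to [segment_epochs()].
#' @return The pipeline output: a recording or an epoch set.
#' @export
apply_pipeline <- function(x, steps, label = 0L, label_names = "unlabeled") {
  for (s in steps) {
    x <- switch(s$step,
      bandpass = bandpass_filter(x, s$low, s$high),
      notch = notch_filter(x, s$freq %||% 50),
      resample = if (inherits(x, "epoch_set")) {
        resample_epochs(x, s$target_rate)
      } else {
        resample_recording(x, s$target_rate)
      },
      segment = segment_epochs(x, s$epoch_seconds %||% 4, s$overlap %||% 0,
                               label = label, label_names = label_names),
      normalize = normalize_epochs(x),
      stop(sprintf("unknown pipeline step '%s'", s$step), call. = FALSE))
  }
  x
}
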