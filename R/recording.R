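# Containers for continuous recordings and labelled epoch sets.

#' Construct a continuous multichannel EEG recording
#'
#' @param signal Numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of channel labels, one per row of
#'   `signal`.
#' @param subject_id,trial_id Identifier strings carried through
#'   preprocessing and segmentation.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_names,
                          subject_id = "s01", trial_id = "t01") {
  signal <- as.matrix(signal)
  assert_that(is.numeric(signal), "signal must be numeric")
  assert_that(is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
                is.finite(sampling_rate) && sampling_rate > 0,
              "sampling_rate must be a positive scalar (Hz)")
  channel_names <- as.character(channel_names)
  assert_that(nrow(signal) == length(channel_names),
              sprintf("channel count mismatch: %d signal rows vs %d channel names",
                      nrow(signal), length(channel_names)))
  structure(
    list(signal = signal, sampling_rate = as.numeric(sampling_rate),
         channel_names = channel_names,
         subject_id = as.character(subject_id),
         trial_id = as.character(trial_id)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), subject %s, trial %s\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate, x$subject_id, x$trial_id))
  invisible(x)
}

#' Construct a labelled epoch set
#'
#' The universal training/evaluation currency: fixed-length segments with one
#' integer class label each.  Labels are 0-based codes into `label_names`.
#'
#' @param epochs Numeric array `[n_epochs, channels, samples]`.
#' @param labels Integer vector of 0-based class codes, one per epoch.
#' @param label_names Character vector of class names (length = number of
#'   classes).
#' @param subject_ids Character vector, one per epoch (needed by
#'   leave-one-subject-out evaluation).
#' @param sampling_rate Hz.
#' @param channel_names Channel labels (length = `dim(epochs)[2]`).
#' @param epoch_seconds Epoch duration in seconds.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, labels, label_names, subject_ids,
                      sampling_rate, channel_names, epoch_seconds) {
  assert_that(is.array(epochs) && length(dim(epochs)) == 3L,
              "epochs must be a 3-d array [n_epochs, channels, samples]")
  n <- dim(epochs)[1]
  labels <- as.integer(labels)
  assert_that(length(labels) == n, "one label per epoch required")
  if (n > 0) {
    assert_that(all(labels >= 0L & labels < length(label_names)),
                "labels must lie in [0, n_classes)")
    assert_that(abs(dim(epochs)[3] - round(epoch_seconds * sampling_rate)) < 1,
                "samples must equal round(epoch_seconds * sampling_rate)")
  }
  subject_ids <- rep_len(as.character(subject_ids), n)
  assert_that(dim(epochs)[2] == length(channel_names),
              "channel name count must match epoch channel dimension")
  structure(
    list(epochs = epochs, labels = labels,
         label_names = as.character(label_names),
         subject_ids = subject_ids,
         sampling_rate = as.numeric(sampling_rate),
         channel_names = as.character(channel_names),
         epoch_seconds = as.numeric(epoch_seconds)),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz; %d classes (%s); %d subjects\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$sampling_rate, length(x$label_names),
              paste(x$label_names, collapse = ", "),
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Subset an epoch set by epoch index
#'
#' @param ep An `epoch_set`.
#' @param idx Integer or logical index over epochs.
#' @return The subsetted `epoch_set` (class list unchanged).
#' @export
subset_epochs <- function(ep, idx) {
  epoch_set(ep$epochs[idx, , , drop = FALSE], ep$labels[idx], ep$label_names,
            ep$subject_ids[idx], ep$sampling_rate, ep$channel_names,
            ep$epoch_seconds)
}

#' Number of epochs in an epoch set
#' @param ep An `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(ep) dim(ep$epochs)[1]
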