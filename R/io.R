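# Reading and writing recordings: EDF (European Data Format) and a simple
# array container (flat binary of doubles plus a JSON sidecar).  No R package
# for EDF ships with this toolchain, so a minimal reader/writer for
# continuous EDF signals (no annotations) is implemented here.

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Minimal EDF writer for continuous signals: one data record per second,
#' all channels at the recording's sampling rate, 16-bit samples scaled to
#' each channel's physical range.  Trailing samples that do not fill a whole
#' record are dropped.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  assert_that(fs == round(fs), "EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signal)
  spr <- as.integer(fs)                    # samples per record (1-s records)
  n_rec <- ncol(rec$signal) %/% spr
  assert_that(n_rec >= 1, "recording shorter than one EDF record (1 s)")
  sig <- rec$signal[, seq_len(n_rec * spr), drop = FALSE]

  pmin <- apply(sig, 1L, min); pmax <- apply(sig, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(rec$subject_id, 80), .edf_pad(rec$trial_id, 80),
    .edf_pad("01.01.26", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad(1, 8), .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) writeChar(paste(vapply(
    vals, .edf_pad, "", width = width), collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin, digits = 6, format = "g"), 8)
  field(formatC(pmax, digits = 6, format = "g"), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, cols] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                                    # version
  subject <- rd(80); recording_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8)); dur <- as.numeric(rd(8)); ns <- as.integer(rd(4))
  assert_that(!is.na(ns) && ns >= 1, sprintf("EDF format error in %s", path))
  rdn <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdn(16); rdn(80); rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80); spr <- as.integer(rdn(8)); rdn(32)
  assert_that(length(unique(spr)) == 1L,
              "EDF reader supports a single sampling rate across channels")
  fs <- spr[1] / dur
  gain <- (pmax - pmin) / (dmax - dmin)
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L,
                     endian = "little", signed = TRUE)
      sig[ch, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  eeg_recording(sig, fs, labels, subject_id = subject, trial_id = recording_id)
}

#' Write a recording as an array container (binary + JSON sidecar)
#'
#' The container is a flat little-endian float64 file holding the
#' channels-x-samples matrix in column-major order, next to a JSON sidecar
#' `<path>.json` carrying the metadata needed to read it back.
#'
#' @param rec An [eeg_recording()].
#' @param path Path of the binary file; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_array_container <- function(rec, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(rec$signal), con, size = 8L, endian = "little")
  close(con)
  meta <- list(sampling_rate = rec$sampling_rate,
               channel_names = rec$channel_names,
               subject_id = rec$subject_id, trial_id = rec$trial_id,
               n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
               dtype = "float64", order = "channels_first_column_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

.read_array_container <- function(path) {
  sidecar <- paste0(path, ".json")
  assert_that(file.exists(sidecar),
              sprintf("missing JSON sidecar %s for array container", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("sampling_rate", "channel_names")) {
    assert_that(!is.null(meta[[f]]),
                sprintf("metadata error: sidecar %s lacks '%s'", sidecar, f))
  }
  nc <- length(meta$channel_names)
  n_bytes <- file.info(path)$size
  vals <- readBin(path, "numeric", n = n_bytes / 8, size = 8L,
                  endian = "little")
  assert_that(length(vals) %% nc == 0,
              sprintf("format error: %d values in %s not divisible by %d channels",
                      length(vals), path, nc))
  if (!is.null(meta$n_samples)) {
    assert_that(length(vals) == nc * meta$n_samples,
                sprintf("format error: %s holds %d values, sidecar promises %d",
                        path, length(vals), nc * meta$n_samples))
  }
  sig <- matrix(vals, nrow = nc)
  eeg_recording(sig, meta$sampling_rate, meta$channel_names,
                subject_id = meta$subject_id %||% "unknown",
                trial_id = meta$trial_id %||% "t01")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a recording from disk
#'
#' @param path Path to an EDF file or the binary part of an array container.
#' @param format `"edf"` or `"array"`; `"auto"` picks `"edf"` for an `.edf`
#'   extension and `"array"` otherwise.
#' @return An [eeg_recording()] with metadata populated and channel order as
#'   stored in the file.
#' @export
load_recording <- function(path, format = c("auto", "edf", "array")) {
  format <- match.arg(format)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "array"
  }
  switch(format, edf = .read_edf(path), array = .read_array_container(path))
}

#' Read a trial-label table
#'
#' Dimensional tables carry columns `subject`, `trial`, `valence`, `arousal`
#' (ratings on a 1-9 scale); discrete tables carry `subject`, `trial`,
#' `label`.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ok <- all(c("subject", "trial") %in% names(tab)) &&
    (all(c("valence", "arousal") %in% names(tab)) || "label" %in% names(tab))
  assert_that(ok, "label table needs subject, trial and valence/arousal or label columns")
  tab
}
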