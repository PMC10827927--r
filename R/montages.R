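# Scalp montage resources: channel names and idealised 2-D coordinates for
# the 32-channel and 62-channel layouts used by the common emotion datasets,
# plus arbitrary custom channel lists.

# Geneva ordering of the 32-channel layout.
.deap32_channels <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2"
)

# 62-channel 10-10 layout (standard extended cap, anterior to posterior).
.seedv62_channels <- c(
  "Fp1", "Fpz", "Fp2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
  "CB1", "O1", "Oz", "O2", "CB2"
)

# Anterior-posterior coordinate of each 10-10 row (head radius 1, nose up).
.row_y <- c(
  Fp = 0.80, AF = 0.62, F = 0.45, FT = 0.22, FC = 0.22, T = 0.00,
  C = 0.00, TP = -0.22, CP = -0.22, P = -0.45, PO = -0.62, O = -0.80,
  CB = -0.90
)

# Nominal lateral fraction for each within-row index (z = midline).
.col_frac <- c("z" = 0, "1" = 0.22, "2" = 0.22, "3" = 0.45, "4" = 0.45,
               "5" = 0.70, "6" = 0.70, "7" = 0.95, "8" = 0.95)

# Parse a 10-10 label into (row prefix, column token, hemisphere sign).
.parse_channel_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|Z|[0-9]+)$", label))[[1]]
  if (length(m) == 0L) return(NULL)
  row <- m[2]
  col <- tolower(m[3])
  if (row %in% c("Fp", "FP")) row <- "Fp"
  if (!(row %in% names(.row_y))) return(NULL)
  if (col == "z") {
    list(row = row, frac = 0, side = 0)
  } else {
    num <- as.integer(col)
    frac <- .col_frac[[as.character(min(num, 8L))]]
    # Frontal-pole and occipital electrodes sit closer to the midline.
    if (row %in% c("Fp", "O", "CB")) frac <- min(frac, 0.35)
    list(row = row, frac = frac, side = if (num %% 2L == 1L) -1 else 1)
  }
}

#' Montage lookup: channel names with 2-D scalp coordinates
#'
#' Returns the channel list and idealised two-dimensional head-frame
#' coordinates (unit-radius disc, nose up, left ear at negative x) for a
#' named montage or an arbitrary list of 10-20/10-10 labels.  Coordinates
#' are computed from the row (anterior-posterior) and within-row (lateral)
#' position of each label, shrunk towards the midline near the frontal pole
#' and occiput so that all electrodes stay on the disc; they are intended
#' for numeric topography reports, not for source modelling.
#'
#' @param montage `"deap32"`, `"seedv62"`, or a character vector of channel
#'   labels (a custom montage).
#' @return A data frame with columns `channel`, `x`, `y`.
#' @examples
#' head(get_montage("deap32"))
#' @export
get_montage <- function(montage) {
  channels <- if (length(montage) == 1L && montage %in% c("deap32", "seedv62")) {
    switch(montage, deap32 = .deap32_channels, seedv62 = .seedv62_channels)
  } else {
    as.character(montage)
  }
  coords <- t(vapply(channels, function(ch) {
    p <- .parse_channel_label(ch)
    if (is.null(p)) return(c(NA_real_, NA_real_))
    y <- .row_y[[p$row]]
    x <- p$side * p$frac * sqrt(max(1 - y^2, 0))
    c(x, y)
  }, numeric(2)))
  data.frame(channel = channels, x = coords[, 1], y = coords[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}
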