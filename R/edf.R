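# Minimal EDF (European Data Format) support: continuous recordings,
# 16-bit samples, one data record per second. Enough to exchange
# ECG/plethysmograph/SpO2 channels with polysomnography software; not a
# general-purpose EDF library (no EDF+ annotations, no discontinuous
# records).

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

#' Write uniform series to a minimal EDF file
#'
#' Encodes one or more channels as a standard EDF (16-bit integers, one
#' 1 s data record per second; channels may have different sampling rates
#' but each rate must be a whole number of samples per second).
#'
#' @param channels Named list of [uniform_series()].
#' @param path Output path.
#' @param patient,recording Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(channels, path, patient = "X", recording = "synthetic") {
  stopifnot(is.list(channels), length(names(channels)) == length(channels))
  ns <- length(channels)
  spr <- vapply(channels, function(ch) {
    stopifnot(inherits(ch, "uniform_series"))
    r <- 1 / ch$step_s
    if (abs(r - round(r)) > 1e-6)
      stop("EDF export needs a whole number of samples per second")
    as.integer(round(r))
  }, integer(1))
  n_rec <- min(vapply(seq_len(ns), function(i)
    floor(length(channels[[i]]$values) / spr[i]), numeric(1)))
  if (n_rec < 1) stop("channels shorter than one 1 s data record")

  phys_min <- vapply(channels, function(ch) min(ch$values, na.rm = TRUE), numeric(1))
  phys_max <- vapply(channels, function(ch) max(ch$values, na.rm = TRUE), numeric(1))
  same <- phys_max - phys_min < 1e-9
  phys_max[same] <- phys_min[same] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording, 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  field(names(channels), 16)                       # label
  field(rep("", ns), 80)                           # transducer
  field(rep("unit", ns), 8)                        # physical dimension
  field(sprintf("%g", phys_min), 8)
  field(sprintf("%g", phys_max), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                           # prefiltering
  field(spr, 8)
  field(rep("", ns), 32)                           # reserved

  gain <- (phys_max - phys_min) / 65535
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- channels[[i]]$values[((r - 1) * spr[i] + 1):(r * spr[i])]
      seg[!is.finite(seg)] <- phys_min[i]
      dig <- as.integer(round((seg - phys_min[i]) / gain[i]) - 32768)
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read channels from a minimal EDF file
#'
#' Supports continuous EDF recordings with 16-bit samples. Channel names
#' are taken from the signal labels.
#'
#' @param path EDF file path.
#' @param channels Optional character vector of channel labels to keep.
#' @return Named list of [uniform_series()].
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchar) trimws(readChar(con, nchar, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                            # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)

  out <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      out[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        phys_min[i] + (dig - dig_min[i]) * gain
    }
  }
  names(out) <- labels
  if (!is.null(channels)) {
    miss <- setdiff(channels, labels)
    if (length(miss))
      stop("channels not present in EDF: ", paste(miss, collapse = ", "))
    out <- out[channels]
  }
  lapply(out, function(v) uniform_series(v, step_s = rec_dur / length(v) *
                                           n_rec))
}
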