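# Minimal EDF (European Data Format) reader/writer: fixed-width ASCII header
# plus 16-bit little-endian data records. Supports the common case needed
# here -- equal sampling rate across signals, continuous records -- and is
# round-trip tested against the CSV path. Physical scaling follows the EDF
# spec: phys = phys_min + (dig - dig_min) * (phys_max - phys_min) / (dig_max - dig_min).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write a recording to an EDF file
#'
#' Writes one [eeg_recording] as a 16-bit EDF file with one-second data
#' records. Values are linearly quantized to the signal's observed range,
#' so the round trip is exact to about `range/65535`.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  nc <- n_channels(rec)
  ns <- n_samples(rec)
  n_rec <- ceiling(ns / fs)
  # pad the tail of the last record with the final sample value
  data <- rec$data
  if (n_rec * fs > ns)
    data <- cbind(data, data[, rep(ns, n_rec * fs - ns), drop = FALSE])

  phys_min <- apply(data, 1, min)
  phys_max <- apply(data, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad(rec$participant_id, 80),
    edf_pad(paste("group:", rec$group), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad((nc + 1) * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(nc, 4)), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)
  field(rep("", nc), 80)                       # transducer
  field(rep("uV", nc), 8)                      # physical dimension
  writeChar(paste(vapply(phys_min, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_max, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  field(rep(dig_min, nc), 8)
  field(rep(dig_max, nc), 8)
  field(rep("", nc), 80)                       # prefiltering
  field(rep(fs, nc), 8)                        # samples per record
  field(rep("", nc), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nc)) {
      dig <- round((data[ch, idx] - phys_min[ch]) / scale[ch]) + dig_min
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Parses the EDF header and 16-bit data records and applies the header's
#' physical scaling. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @param participant_id,group metadata attached to the returned recording;
#'   `participant_id` defaults to the EDF patient field.
#' @return An [eeg_recording].
#' @export
read_edf <- function(path, participant_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, w) trimws(substr(s, from, from + w - 1))
  patient <- fld(hdr, 9, 80)
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  nc <- as.integer(fld(hdr, 253, 4))
  if (is.na(nc) || nc < 1) stop("unparseable EDF header: bad signal count", call. = FALSE)
  sig <- readChar(con, nc * 256, useBytes = TRUE)
  take <- function(block_off, w) {
    vapply(seq_len(nc) - 1L,
           function(i) trimws(substr(sig, block_off + i * w + 1, block_off + (i + 1) * w)),
           "")
  }
  labels   <- take(0L, 16L)
  phys_min <- as.numeric(take(nc * (16 + 80 + 8), 8L))
  phys_max <- as.numeric(take(nc * (16 + 80 + 8 + 8), 8L))
  dig_min  <- as.numeric(take(nc * (16 + 80 + 8 + 8 + 8), 8L))
  dig_max  <- as.numeric(take(nc * (16 + 80 + 8 + 8 + 8 + 8), 8L))
  spr      <- as.integer(take(nc * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8L))
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate; header has ",
         paste(unique(spr), collapse = "/"), " samples per record", call. = FALSE)
  fs <- spr[1] / rec_dur

  raw <- readBin(con, "integer", n = n_rec * nc * spr[1], size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) != n_rec * nc * spr[1])
    stop("EDF data truncated: expected ", n_rec * nc * spr[1],
         " samples, read ", length(raw), call. = FALSE)
  data <- matrix(0, nc, n_rec * spr[1])
  # records are interleaved: [rec1: sig1..sigNC][rec2: ...]
  arr <- array(raw, dim = c(spr[1], nc, n_rec))
  for (ch in seq_len(nc)) {
    dig <- as.vector(arr[, ch, ])
    data[ch, ] <- phys_min[ch] +
      (dig - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  }
  eeg_recording(data, fs_hz = fs, channel_labels = labels,
                participant_id = if (is.null(participant_id)) patient else participant_id,
                group = group)
}
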