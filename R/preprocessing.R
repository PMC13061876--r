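#' Write a recording as CSV
#'
#' Comma-separated, one header row of channel labels, rows = samples (time
#' runs down the file). The sampling rate is not stored in the CSV and must
#' be supplied again on read.
#'
#' @param rec an [eeg_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an EEG recording from EDF or CSV
#'
#' CSV files follow the dialect of [write_recording_csv()] (header row of
#' channel labels, samples as rows) and need an explicit `fs_hz`; EDF files
#' carry their own rate and labels.
#'
#' @param path file path.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by file extension).
#' @param fs_hz sampling rate in Hz; required for CSV, ignored for EDF.
#' @param participant_id,group metadata for the returned recording.
#' @return An [eeg_recording].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"), fs_hz = NULL,
                           participant_id = NULL, group = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (format == "edf")
    return(read_edf(path, participant_id = participant_id, group = group))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(fs_hz)) stop("`fs_hz` is required for CSV input", call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate channel labels in CSV header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  eeg_recording(t(as.matrix(df)), fs_hz = fs_hz, channel_labels = names(df),
                participant_id = if (is.null(participant_id))
                  tools::file_path_sans_ext(basename(path)) else participant_id,
                group = group)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]), giving zero phase distortion -- required so the
#' instantaneous frequency downstream is not biased by group delay. The
#' default analysis band is 4-13 Hz (theta + alpha); the alpha-only variant
#' is `low_hz = 8`. DC is removed by the band-pass itself.
#'
#' @param rec an [eeg_recording].
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of the one-way filter (effective order is
#'   doubled by the forward-backward pass).
#' @return A filtered [eeg_recording] of the same shape.
#' @export
bandpass <- function(rec, low_hz = 4, high_hz = 13, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("band [%g, %g] Hz invalid for fs = %g Hz (need 0 < low < high < %g)",
                 low_hz, high_hz, rec$fs_hz, nyq), call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Trim filter-edge segments
#'
#' Removes `trim_s` seconds from both ends of the recording, discarding
#' filter and Hilbert-transform edge effects. Interior samples are
#' untouched.
#'
#' @param rec an [eeg_recording].
#' @param trim_s seconds to drop from each end; `2 * trim_s` must be less
#'   than the recording duration.
#' @return A shorter [eeg_recording].
#' @export
trim_edges <- function(rec, trim_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (trim_s < 0) stop("`trim_s` must be >= 0", call. = FALSE)
  if (trim_s == 0) return(rec)
  n_trim <- round(trim_s * rec$fs_hz)
  n <- n_samples(rec)
  if (2 * n_trim >= n)
    stop(sprintf("cannot trim %g s from each end of a %.3g s recording",
                 trim_s, n / rec$fs_hz), call. = FALSE)
  out <- rec
  out$data <- rec$data[, (n_trim + 1):(n - n_trim), drop = FALSE]
  out
}
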