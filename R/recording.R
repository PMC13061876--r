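#' Multichannel EEG recording
#'
#' Container for one participant's EEG segment: a channels x samples numeric
#' matrix together with its sampling rate, ordered channel labels, a
#' participant identifier and a group label. All downstream stages
#' (band-pass filtering, instantaneous-frequency extraction, state decoding)
#' consume and return this class.
#'
#' @param data numeric matrix, channels x samples (microvolts or arbitrary
#'   units). Row names, if present, are used as channel labels when
#'   `channel_labels` is missing.
#' @param fs_hz sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of unique channel names (10-20
#'   positions for scalp EEG), one per row of `data`.
#' @param participant_id participant identifier string.
#' @param group group label (e.g. `"younger"` / `"middle_aged"`), or `NA`.
#' @return An object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(2 * 400), 2)
#' rec <- eeg_recording(x, fs_hz = 200, channel_labels = c("O1", "O2"))
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs_hz, channel_labels = rownames(data),
                          participant_id = "p1", group = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  if (nrow(data) < 2L)
    stop("a recording needs at least 2 channels, got ", nrow(data), call. = FALSE)
  if (!all(is.finite(data)))
    stop("`data` contains non-finite samples", call. = FALSE)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("`fs_hz` must be a positive scalar", call. = FALSE)
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("length(channel_labels) != number of rows of `data`", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "),
         call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs_hz = as.numeric(fs_hz),
         channel_labels = channel_labels,
         participant_id = as.character(participant_id),
         group = as.character(group)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$participant_id, x$group, nrow(x$data), ncol(x$data), x$fs_hz,
              ncol(x$data) / x$fs_hz))
  invisible(x)
}

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname eeg_recording
#' @export
n_channels <- function(rec) nrow(rec$data)

#' The 16-electrode 10-20 montage used by default
#'
#' Standard labels for a 16-channel clinical montage, ordered
#' anterior-to-posterior. Used as the default channel set of the synthetic
#' cohort generator so spatial patterns can be described as frontal or
#' occipital.
#' @return character vector of length 16.
#' @export
default_channel_labels <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "F7", "F8",
    "C3", "C4", "P3", "Pz", "P4", "T5", "T6", "O1", "O2")
}
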