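#' Analytic signal of a band-limited recording
#'
#' Computes the analytic signal a(t) = x(t) + i H\[x\](t) of every channel
#' via the FFT construction (positive frequencies doubled, negative zeroed):
#' the real part equals the input exactly and the imaginary part is the
#' Hilbert transform. The argument of a(t) is the instantaneous phase and
#' its modulus the instantaneous amplitude.
#'
#' @param rec a band-limited [eeg_recording].
#' @return Object of class `analytic_signal`: complex channels x samples
#'   matrix plus `fs_hz` and `channel_labels`.
#' @export
analytic_signal <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  a <- t(apply(rec$data, 1, function(x) fft(fft(x) * h, inverse = TRUE) / n))
  # the real part is the input by construction; enforce it against FFT rounding
  a <- complex(real = rec$data, imaginary = Im(a))
  dim(a) <- dim(rec$data)
  rownames(a) <- rec$channel_labels
  structure(list(a = a, fs_hz = rec$fs_hz, channel_labels = rec$channel_labels),
            class = "analytic_signal")
}

#' Wrapped instantaneous phase
#'
#' Element-wise argument of the analytic signal, in (-pi, pi]. A channel
#' whose analytic signal is identically zero has no defined phase and is an
#' error.
#'
#' @param a an `analytic_signal` (or bare complex matrix).
#' @return channels x samples matrix of wrapped phase (radians).
#' @export
wrapped_phase <- function(a) {
  m <- if (inherits(a, "analytic_signal")) a$a else a
  zero <- apply(m, 1, function(r) all(Mod(r) == 0))
  if (any(zero)) {
    who <- rownames(m)[zero]
    if (is.null(who)) who <- which(zero)
    stop("phase undefined for all-zero channel(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  Arg(m)
}

#' Unwrap phase along time
#'
#' Adds integer multiples of 2*pi per sample so successive differences lie
#' in (-pi, pi]; the output differs from the input by an element of 2*pi*Z
#' everywhere. Idempotent.
#'
#' @param phase channels x samples matrix (or vector) of wrapped phase.
#' @return matrix of the same shape.
#' @export
unwrap_phase <- function(phase) {
  if (is.vector(phase)) return(signal::unwrap(phase))
  out <- t(apply(phase, 1, signal::unwrap))
  dimnames(out) <- dimnames(phase)
  out
}

#' Instantaneous frequency from unwrapped phase
#'
#' IF(t) = (1/2*pi) d phi/dt, estimated by central differences at interior
#' samples and one-sided differences at the two ends, so the output has the
#' same length as the input.
#'
#' @param phase unwrapped-phase matrix (channels x samples) or vector.
#' @param fs_hz sampling rate in Hz.
#' @return matrix/vector of raw instantaneous frequency in Hz.
#' @export
phase_derivative <- function(phase, fs_hz) {
  deriv1 <- function(p) {
    n <- length(p)
    if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
    d <- numeric(n)
    d[2:(n - 1)] <- (p[3:n] - p[1:(n - 2)]) * (fs_hz / 2)
    d[1] <- (p[2] - p[1]) * fs_hz
    d[n] <- (p[n] - p[n - 1]) * fs_hz
    d / (2 * pi)
  }
  if (is.vector(phase)) return(deriv1(phase))
  out <- t(apply(phase, 1, deriv1))
  dimnames(out) <- dimnames(phase)
  out
}

#' Running-median smoothing of instantaneous frequency
#'
#' Length-preserving running median with a centered window of
#' `round(window_ms * fs / 1000)` samples, forced odd (rounded up), e.g. 21
#' samples for 100 ms at 200 Hz. Near the ends the median is taken over the
#' samples actually available. The median filter suppresses the brief
#' spikes that phase slips leave in the raw IF; out-of-band values that
#' survive it are retained, not clipped.
#'
#' @param x numeric matrix (channels x samples) or vector.
#' @param fs_hz sampling rate in Hz.
#' @param window_ms window length in milliseconds (default 100).
#' @return smoothed matrix/vector, same shape.
#' @export
median_smooth <- function(x, fs_hz, window_ms = 100) {
  k <- round(window_ms * fs_hz / 1000)
  if (k %% 2 == 0) k <- k + 1
  k <- max(k, 1L)
  smooth1 <- function(v) {
    n <- length(v)
    if (k == 1 || n == 1) return(v)
    kk <- min(k, if (n %% 2 == 1) n else n - 1)
    out <- as.numeric(stats::runmed(v, kk, endrule = "keep"))
    half <- (kk - 1) / 2
    for (i in seq_len(min(half, n))) {           # shrinking windows at edges
      out[i] <- median(v[1:min(n, i + half)])
      j <- n - i + 1
      out[j] <- median(v[max(1, j - half):n])
    }
    out
  }
  if (is.vector(x)) return(smooth1(x))
  out <- t(apply(x, 1, smooth1))
  dimnames(out) <- dimnames(x)
  out
}

#' Smoothed instantaneous-frequency series for a recording
#'
#' End-to-end IF extraction: analytic signal, wrapped phase, unwrapping,
#' phase derivative, median smoothing. Input should already be band-pass
#' filtered to the analysis band (see [bandpass()]).
#'
#' @param rec a band-limited [eeg_recording].
#' @param window_ms median-filter window in milliseconds.
#' @return Object of class `if_series`: `if_hz` (channels x samples, Hz),
#'   `fs_hz`, `channel_labels`, `participant_id`, `group`.
#' @examples
#' t <- seq(0, 3, by = 1 / 200)[-1]
#' rec <- eeg_recording(rbind(cos(2 * pi * 10 * t), sin(2 * pi * 8 * t)),
#'                      fs_hz = 200, channel_labels = c("a", "b"))
#' ifs <- extract_if(rec)
#' rowMeans(ifs$if_hz[, 100:500])  # ~10 and ~8 Hz
#' @export
extract_if <- function(rec, window_ms = 100) {
  a <- analytic_signal(rec)
  phi <- wrapped_phase(a)
  raw <- phase_derivative(unwrap_phase(phi), rec$fs_hz)
  structure(
    list(if_hz = median_smooth(raw, rec$fs_hz, window_ms),
         fs_hz = rec$fs_hz, channel_labels = rec$channel_labels,
         participant_id = rec$participant_id, group = rec$group),
    class = "if_series")
}

#' @export
print.if_series <- function(x, ...) {
  cat(sprintf("<if_series> %s [%s]: %d channels x %d samples @ %g Hz\n",
              x$participant_id, x$group, nrow(x$if_hz), ncol(x$if_hz), x$fs_hz))
  invisible(x)
}
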