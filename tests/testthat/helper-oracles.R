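# Independent brute-force oracles used across test files. These stay naive
# on purpose: direct loops and definitions, no shared code with the package
# internals they check.

# direct O(n K^2) recount of all dynamics metrics from a label vector
brute_metrics <- function(labels, fs, K) {
  n <- length(labels)
  dwell_lists <- vector("list", K)
  run_val <- labels[1]; run_len <- 1L
  for (t in seq_len(n)[-1]) {
    if (labels[t] == run_val) run_len <- run_len + 1L
    else {
      dwell_lists[[run_val]] <- c(dwell_lists[[run_val]], run_len)
      run_val <- labels[t]; run_len <- 1L
    }
  }
  dwell_lists[[run_val]] <- c(dwell_lists[[run_val]], run_len)
  counts <- matrix(0L, K, K)
  for (t in seq_len(n - 1))
    counts[labels[t], labels[t + 1]] <- counts[labels[t], labels[t + 1]] + 1L
  occ <- numeric(K)
  for (k in 1:K) occ[k] <- sum(labels == k) / n
  probs <- matrix(NA_real_, K, K)
  for (i in 1:K) {
    tot <- sum(counts[i, ])
    if (tot > 0) probs[i, ] <- counts[i, ] / tot
  }
  list(
    mean_dwell_s = vapply(dwell_lists, function(d)
      if (is.null(d)) NA_real_ else mean(d) / fs, 0),
    occupancy = occ,
    n_episodes = vapply(dwell_lists, function(d) length(d), 0L),
    counts = counts, probs = probs)
}

# Benjamini-Hochberg step-up, from the definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  if (m > 1)
    for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# small band-limited test recording: sum of named sinusoids
sine_recording <- function(freqs, fs = 200, dur = 10, labels = NULL) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  data <- t(vapply(freqs, function(f) cos(2 * pi * f * t), t))
  if (is.null(labels)) labels <- paste0("ch", seq_along(freqs))
  eeg_recording(data, fs_hz = fs, channel_labels = labels)
}

central_idx <- function(n, frac = 0.8) {
  drop <- floor(n * (1 - frac) / 2)
  (drop + 1):(n - drop)
}

# spatial_pattern_series wrapper for bare matrices (tests that feed the HMM
# directly with generated observations)
as_sps <- function(X, id = "p1", group = "g", fs = 200) {
  structure(list(z = X, degenerate = rep(FALSE, nrow(X)), participant_id = id,
                 group = group, fs_hz = fs,
                 channel_labels = colnames(X)),
            class = "spatial_pattern_series")
}
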