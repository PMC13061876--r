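#' Markov-chain specification
#'
#' Transition structure for the hidden state process: a K x K row-stochastic
#' transition matrix and an initial distribution. Validated on
#' construction.
#'
#' @param transition_matrix K x K matrix; every row must sum to 1 (within
#'   1e-12) with entries in \[0, 1\].
#' @param initial_distribution length-K probability vector; defaults to
#'   uniform.
#' @return Object of class `markov_spec`.
#' @examples
#' markov_spec(matrix(c(0.94, 0.06, 0.06, 0.94), 2, byrow = TRUE))
#' @export
markov_spec <- function(transition_matrix,
                        initial_distribution = rep(1 / nrow(transition_matrix),
                                                   nrow(transition_matrix))) {
  A <- as.matrix(transition_matrix)
  K <- nrow(A)
  if (K < 2 || ncol(A) != K)
    stop("`transition_matrix` must be square with K >= 2", call. = FALSE)
  if (any(A < 0) || any(A > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  bad <- abs(rowSums(A) - 1) > 1e-12
  if (any(bad))
    stop("transition matrix rows ", paste(which(bad), collapse = ", "),
         " do not sum to 1", call. = FALSE)
  p <- as.numeric(initial_distribution)
  if (length(p) != K || any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("`initial_distribution` must be a length-K probability vector", call. = FALSE)
  structure(list(n_states = K, transition_matrix = A, initial_distribution = p),
            class = "markov_spec")
}

#' Uniform-off-diagonal Markov spec
#'
#' Convenience constructor: state k self-transitions with probability
#' `self[k]` and spreads the remainder uniformly over the other states.
#' Self-transition around 0.94 at 200 Hz gives mean dwell times near 80 ms,
#' the scale seen in resting-state IF microstates.
#'
#' @param self scalar or length-K vector of self-transition probabilities.
#' @param K number of states (default `length(self)` if `self` is a vector,
#'   else required).
#' @return A [markov_spec].
#' @export
sticky_markov_spec <- function(self = 0.94, K = max(length(self), 2L)) {
  self <- rep_len(self, K)
  A <- matrix(0, K, K)
  for (k in seq_len(K)) {
    A[k, ] <- (1 - self[k]) / (K - 1)
    A[k, k] <- self[k]
  }
  markov_spec(A)
}

#' Sample a first-order Markov state sequence
#'
#' @param spec a [markov_spec].
#' @param n_samples sequence length (>= 1).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return integer vector of labels in 1..K.
#' @export
sample_markov_chain <- function(spec, n_samples, seed) {
  stopifnot(inherits(spec, "markov_spec"))
  if (n_samples < 1) stop("`n_samples` must be >= 1", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  u <- runif(n_samples)
  cumA <- t(apply(spec$transition_matrix, 1, cumsum))
  markov_path_cpp(cumA, cumsum(spec$initial_distribution), u)
}

# preserve the caller's RNG stream around seeded draws
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Spatial IF pattern of one synthetic state
#'
#' A state is a vector of per-channel frequency offsets (Hz) added to the
#' cohort's carrier frequency while the state is active; e.g. positive
#' occipital and negative frontal offsets produce an occipital-fast /
#' frontal-slow gradient.
#'
#' @param state_id integer label.
#' @param channel_freq_offsets numeric vector of finite offsets (Hz), one
#'   per channel.
#' @return Object of class `state_pattern_spec`.
#' @export
state_pattern_spec <- function(state_id, channel_freq_offsets) {
  off <- as.numeric(channel_freq_offsets)
  if (!all(is.finite(off)))
    stop("channel frequency offsets must be finite", call. = FALSE)
  structure(list(state_id = as.integer(state_id), channel_freq_offsets = off),
            class = "state_pattern_spec")
}

#' Default five-state spatial pattern set
#'
#' Five distinct spatial IF patterns over the default 16-channel montage,
#' built from an anterior-posterior gradient score: an occipital-lead /
#' frontal-lag state, its reverse, a left-right asymmetry, a midline-fast
#' state, and a temporo-occipital-fast state. Offsets are within +/- 1 Hz
#' of the carrier.
#'
#' @param channel_labels channel set; defaults to [default_channel_labels()].
#' @return list of [state_pattern_spec], one per state.
#' @export
default_patterns <- function(channel_labels = default_channel_labels()) {
  g <- vapply(channel_labels, function(ch) {
    switch(substr(ch, 1, 2),
           Fp = -1, F3 = -0.6, Fz = -0.6, F4 = -0.6, F7 = -0.6, F8 = -0.6,
           C3 = 0, C4 = 0,
           P3 = 0.6, Pz = 0.6, P4 = 0.6, T5 = 0.6, T6 = 0.6,
           O1 = 1, O2 = 1, 0)
  }, 0)
  left  <- channel_labels %in% c("Fp1", "F3", "F7", "C3", "P3", "T5", "O1")
  right <- channel_labels %in% c("Fp2", "F4", "F8", "C4", "P4", "T6", "O2")
  mid   <- channel_labels %in% c("Fz", "Pz", "C3", "C4")
  tocc  <- channel_labels %in% c("T5", "T6", "O1", "O2")
  front <- substr(channel_labels, 1, 1) == "F"
  list(
    state_pattern_spec(1,  0.8 * g),                      # occipital lead
    state_pattern_spec(2, -0.8 * g),                      # frontal lead
    state_pattern_spec(3,  0.7 * left - 0.7 * right),     # left fast
    state_pattern_spec(4,  0.8 * mid - 0.3 * !mid),       # midline fast
    state_pattern_spec(5,  0.9 * tocc + 0.2 * front - 0.4 * (!tocc & !front)))
}

#' Synthetic cohort specification
#'
#' Study-level parameters of the simulator. Defaults mirror a two-group
#' resting-state design: 29 younger + 18 middle-aged participants, 16
#' channels, 200 Hz, 60 s, a 10 Hz carrier, and five states with
#' self-transition probabilities near 0.94; the middle-aged group dwells
#' longer in state 1 (self 0.95) and shorter in state 5 (self 0.93), the
#' younger group uses 0.94 throughout. The group contrast lives entirely in
#' the Markov dynamics: spatial patterns are shared.
#'
#' @param n_per_group named integer vector, participants per group.
#' @param base_freq_hz carrier frequency (Hz).
#' @param group_markov named list of [markov_spec], one per group.
#' @param patterns list of [state_pattern_spec] shared by all groups.
#' @param noise_sd additive Gaussian noise SD relative to the unit
#'   oscillation amplitude.
#' @param fs_hz sampling rate (Hz); must exceed twice the maximal
#'   instantaneous frequency.
#' @param duration_s segment length (s).
#' @param seed master seed; per-participant seeds are derived from it.
#' @param channel_labels channel names.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(younger = 29, middle_aged = 18),
                        base_freq_hz = 10,
                        group_markov = NULL,
                        patterns = default_patterns(channel_labels),
                        noise_sd = 0.2,
                        fs_hz = 200, duration_s = 60, seed = 1,
                        channel_labels = default_channel_labels()) {
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("group", seq_along(n_per_group))
  K <- length(patterns)
  if (is.null(group_markov)) {
    group_markov <- list(
      sticky_markov_spec(rep(0.94, K)),
      sticky_markov_spec(c(0.95, rep(0.94, K - 2), 0.93)))
    group_markov <- group_markov[seq_along(n_per_group)]
    names(group_markov) <- names(n_per_group)
  }
  if (!identical(sort(names(group_markov)), sort(names(n_per_group))))
    stop("`group_markov` must carry one markov_spec per group", call. = FALSE)
  offs <- vapply(patterns, function(p) p$channel_freq_offsets,
                 numeric(length(channel_labels)))
  if (any(base_freq_hz + offs <= 0) || any(base_freq_hz + offs >= fs_hz / 2))
    stop("instantaneous frequency leaves (0, fs/2): adjust offsets/carrier/fs",
         call. = FALSE)
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  for (gm in group_markov)
    if (gm$n_states != K) stop("group markov_spec K != number of patterns", call. = FALSE)
  structure(list(n_per_group = n_per_group, base_freq_hz = base_freq_hz,
                 group_markov = group_markov, patterns = patterns,
                 noise_sd = noise_sd, fs_hz = fs_hz, duration_s = duration_s,
                 seed = as.integer(seed), channel_labels = channel_labels),
            class = "cohort_spec")
}

#' Derive a per-participant seed from the master seed
#'
#' Deterministic integer mix of (master seed, group index, participant
#' index); stays below 2^31 so it is a valid R seed. Distinct participants
#' get distinct seeds for any master seed below 2^20.
#' @param master master seed.
#' @param group_index,participant_index 1-based indices.
#' @return integer seed.
#' @export
derive_seed <- function(master, group_index, participant_index) {
  m <- 2147483587  # large prime < 2^31
  s <- (as.numeric(master) %% m) * 48271 %% m
  s <- (s + group_index * 1299709 + participant_index * 7919) %% m
  as.integer(s)
}

#' Synthesize one recording from a known state sequence
#'
#' Observation model: each channel is a unit-amplitude cosine whose
#' instantaneous frequency is `base_freq + offset_channel(state(t))`; the
#' phase accumulates as the integral of the instantaneous frequency, so it
#' is continuous across state switches and the spatial IF pattern is exact
#' ground truth. White Gaussian noise of SD `noise_sd` is added.
#'
#' @param patterns list of [state_pattern_spec] (one per state).
#' @param truth_sequence integer state labels, one per sample.
#' @param cohort a [cohort_spec] (carrier, fs, noise, channels).
#' @param participant_seed integer seed for initial phases and noise.
#' @param participant_id,group metadata.
#' @return list with `recording` ([eeg_recording]) and `ground_truth`
#'   (state sequence, patterns, seed).
#' @export
synthesize_recording <- function(patterns, truth_sequence, cohort,
                                 participant_seed, participant_id = "p1",
                                 group = NA_character_) {
  K <- length(patterns)
  if (!all(truth_sequence %in% seq_len(K)))
    stop("truth_sequence labels outside 1..K", call. = FALSE)
  nch <- length(cohort$channel_labels)
  offs <- vapply(patterns, function(p) {
    if (length(p$channel_freq_offsets) != nch)
      stop("pattern length != channel count", call. = FALSE)
    p$channel_freq_offsets
  }, numeric(nch))                      # nch x K
  freq <- cohort$base_freq_hz + offs    # nch x K instantaneous frequencies
  if (any(freq <= 0) || any(freq >= cohort$fs_hz / 2))
    stop("instantaneous frequency leaves (0, fs/2)", call. = FALSE)
  n <- length(truth_sequence)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(participant_seed)
  phi0 <- runif(nch, 0, 2 * pi)
  f_t <- freq[, truth_sequence, drop = FALSE]          # nch x n
  # phase(t) = phi0 + 2*pi * integral of IF, with sample t's state active on
  # the interval [t - 1/2, t + 1/2] so the measured (central-difference) IF
  # is centered on the labelled sample rather than shifted by half a sample
  phase <- (2 * pi / cohort$fs_hz) * (t(apply(f_t, 1, cumsum)) - f_t / 2) + phi0
  x <- cos(phase)
  if (cohort$noise_sd > 0)
    x <- x + matrix(rnorm(nch * n, sd = cohort$noise_sd), nch, n)
  rec <- eeg_recording(x, fs_hz = cohort$fs_hz,
                       channel_labels = cohort$channel_labels,
                       participant_id = participant_id, group = group)
  list(recording = rec,
       ground_truth = list(state_sequence = as.integer(truth_sequence),
                           patterns = patterns, seed = participant_seed))
}

#' Generate a full synthetic cohort
#'
#' Samples one hidden state sequence per participant from that group's
#' Markov spec and synthesizes the corresponding multichannel recording.
#' All randomness derives from the master seed via [derive_seed()], so the
#' cohort is bit-reproducible.
#'
#' @param cohort a [cohort_spec].
#' @return list of participant entries, each with `recording`,
#'   `ground_truth`, and `group`; the cohort spec is attached as
#'   `attr(, "cohort_spec")`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(a = 2, b = 2), duration_s = 2, seed = 7)
#' coh <- make_cohort(spec)
#' length(coh)
#' @export
make_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  n <- round(cohort$duration_s * cohort$fs_hz)
  out <- list()
  for (g in seq_along(cohort$n_per_group)) {
    gname <- names(cohort$n_per_group)[g]
    mk <- cohort$group_markov[[gname]]
    np <- cohort$n_per_group[[g]]
    if (np < 1) next
    for (j in seq_len(np)) {
      sd_pj <- derive_seed(cohort$seed, g, j)
      labels <- sample_markov_chain(mk, n, seed = sd_pj)
      pid <- sprintf("%s_%02d", gname, j)
      entry <- synthesize_recording(cohort$patterns, labels, cohort,
                                    participant_seed = sd_pj + 1L,
                                    participant_id = pid, group = gname)
      entry$ground_truth$markov_spec <- mk
      entry$group <- gname
      out[[pid]] <- entry
    }
  }
  attr(out, "cohort_spec") <- cohort
  out
}

#' Write a synthetic cohort to disk
#'
#' One file per participant (CSV or EDF) plus a JSON sidecar with the
#' ground-truth state sequence, generating Markov matrix, and seeds.
#'
#' @param cohort_data result of [make_cohort()].
#' @param dir output directory (created if missing).
#' @param format `"csv"` or `"edf"`.
#' @return invisibly, the vector of data-file paths.
#' @export
write_cohort <- function(cohort_data, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (entry in cohort_data) {
    rec <- entry$recording
    base <- file.path(dir, rec$participant_id)
    p <- paste0(base, ".", format)
    if (format == "csv") write_recording_csv(rec, p) else write_edf(rec, p)
    gt <- entry$ground_truth
    jsonlite::write_json(
      list(participant_id = rec$participant_id, group = entry$group,
           fs_hz = rec$fs_hz, seed = gt$seed,
           state_sequence = gt$state_sequence,
           transition_matrix = gt$markov_spec$transition_matrix,
           patterns = lapply(gt$patterns, function(pp)
             list(state_id = pp$state_id, offsets = pp$channel_freq_offsets))),
      paste0(base, "_truth.json"), auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
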