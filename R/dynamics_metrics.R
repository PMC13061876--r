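#' Episode durations per state
#'
#' Run-length encodes a decoded state sequence: each maximal run of one
#' label is an episode, of duration run length / fs seconds. Episodes
#' truncated by the segment boundaries are included.
#'
#' @param seq a `state_sequence` from [decode()], or a bare integer label
#'   vector (then `fs_hz` and `n_states` are needed).
#' @param fs_hz,n_states used only for bare label vectors.
#' @return named list, one numeric vector of episode durations (s) per
#'   state; states that never occur get `numeric(0)`.
#' @export
episodes <- function(seq, fs_hz = NULL, n_states = NULL) {
  s <- as_state_sequence(seq, fs_hz, n_states)
  r <- rle(s$labels)
  out <- lapply(seq_len(s$n_states), function(k)
    r$lengths[r$values == k] / s$fs_hz)
  names(out) <- paste0("state", seq_len(s$n_states))
  out
}

as_state_sequence <- function(seq, fs_hz, n_states) {
  if (inherits(seq, "state_sequence")) return(seq)
  if (is.null(fs_hz) || is.null(n_states))
    stop("bare label vectors need `fs_hz` and `n_states`", call. = FALSE)
  if (length(seq) < 1) stop("empty state sequence", call. = FALSE)
  structure(list(labels = as.integer(seq), participant_id = "p1",
                 group = NA_character_, fs_hz = fs_hz,
                 n_states = as.integer(n_states)),
            class = "state_sequence")
}

#' Mean dwell time per state
#'
#' Arithmetic mean of the state's episode durations, in seconds. States
#' with no episodes are `NA` (absent, not zero-duration).
#'
#' @inheritParams episodes
#' @return numeric vector, one value per state.
#' @export
mean_dwell <- function(seq, fs_hz = NULL, n_states = NULL) {
  ep <- episodes(seq, fs_hz, n_states)
  vapply(ep, function(d) if (length(d)) mean(d) else NA_real_, 0)
}

#' Fractional occupancy per state
#'
#' Total time spent in each state divided by the total duration T; absent
#' states have occupancy 0 and the occupancies sum to 1.
#'
#' @inheritParams episodes
#' @return numeric vector of fractions in \[0, 1\].
#' @export
occupancy <- function(seq, fs_hz = NULL, n_states = NULL) {
  s <- as_state_sequence(seq, fs_hz, n_states)
  tabulate(s$labels, nbins = s$n_states) / length(s$labels)
}

#' Empirical transition probabilities
#'
#' Counts ordered consecutive-sample pairs (including self-transitions)
#' and normalizes each row by its outgoing total:
#' P(i -> j) = N(i -> j) / sum_k N(i -> k). Rows of states with no
#' outgoing transitions are `NA` (missing, not zero).
#'
#' @inheritParams episodes
#' @return list with `probabilities` (K x K) and integer `counts` (K x K).
#' @export
transition_probabilities <- function(seq, fs_hz = NULL, n_states = NULL) {
  s <- as_state_sequence(seq, fs_hz, n_states)
  if (length(s$labels) < 2)
    stop("transition probabilities need a sequence of length >= 2", call. = FALSE)
  counts <- transition_counts_cpp(s$labels, s$n_states)
  tot <- rowSums(counts)
  probs <- counts / tot            # rows with tot == 0 become NA by 0/0
  probs[tot == 0, ] <- NA_real_
  dimnames(counts) <- dimnames(probs) <-
    list(paste0("state", seq_len(s$n_states)), paste0("state", seq_len(s$n_states)))
  list(probabilities = probs, counts = counts)
}

#' All dynamics metrics for one decoded sequence
#'
#' Bundles mean dwell times, occupancies, episode counts and durations,
#' episode rate (episodes per second, the conventional "occurrence"
#' reading), and the empirical transition matrix for one participant --
#' the unit of the downstream group statistics.
#'
#' @inheritParams episodes
#' @return Object of class `dynamics_metrics` with fields `mean_dwell_s`,
#'   `occupancy`, `n_episodes`, `episode_rate_hz`, `episode_durations`,
#'   `transition_matrix`, `transition_counts`, `total_duration_s`,
#'   `participant_id`, `group`.
#' @export
dynamics_metrics <- function(seq, fs_hz = NULL, n_states = NULL) {
  s <- as_state_sequence(seq, fs_hz, n_states)
  ep <- episodes(s)
  tp <- transition_probabilities(s)
  total_s <- length(s$labels) / s$fs_hz
  structure(
    list(mean_dwell_s = vapply(ep, function(d) if (length(d)) mean(d) else NA_real_, 0),
         occupancy = occupancy(s),
         n_episodes = vapply(ep, length, 0L),
         episode_rate_hz = vapply(ep, length, 0L) / total_s,
         episode_durations = ep,
         transition_matrix = tp$probabilities,
         transition_counts = tp$counts,
         total_duration_s = total_s,
         participant_id = s$participant_id, group = s$group),
    class = "dynamics_metrics")
}

#' @export
print.dynamics_metrics <- function(x, ...) {
  cat(sprintf("<dynamics_metrics> %s [%s]: T = %g s\n",
              x$participant_id, x$group, x$total_duration_s))
  print(round(rbind(mean_dwell_s = x$mean_dwell_s, occupancy = x$occupancy), 4))
  invisible(x)
}

#' Tidy per-participant metrics table
#'
#' Long-format data frame over a list of [dynamics_metrics()] results: one
#' row per participant x state with dwell, occupancy, episode count and
#' rate, plus one row per participant x ordered state pair with the
#' transition probability. The format consumed by [compare_metrics()].
#'
#' @param metrics_list list of `dynamics_metrics`.
#' @return data.frame with columns `participant_id`, `group`, `metric`,
#'   `from_state`, `to_state` (NA for per-state metrics), `state`, `value`.
#' @export
tidy_metrics <- function(metrics_list) {
  rows <- lapply(metrics_list, function(m) {
    K <- length(m$mean_dwell_s)
    per_state <- data.frame(
      participant_id = m$participant_id, group = m$group,
      metric = rep(c("mean_dwell_s", "occupancy", "episode_rate_hz"), each = K),
      state = rep(seq_len(K), 3), from_state = NA_integer_, to_state = NA_integer_,
      value = c(m$mean_dwell_s, m$occupancy, m$episode_rate_hz))
    idx <- expand.grid(from_state = seq_len(K), to_state = seq_len(K))
    trans <- data.frame(
      participant_id = m$participant_id, group = m$group,
      metric = "transition_probability", state = NA_integer_,
      from_state = idx$from_state, to_state = idx$to_state,
      value = m$transition_matrix[cbind(idx$from_state, idx$to_state)])
    rbind(per_state, trans)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
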