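#' Per-timepoint spatial normalization of IF series
#'
#' At every sample the mean across electrodes is subtracted from the
#' channel IF values and the result is divided by the across-electrode
#' population (N) standard deviation, yielding a z-scored spatial pattern.
#' Rows with zero spatial variance carry no pattern information; they are
#' flagged (`degenerate`) and excluded from model fitting, not dropped from
#' the time base.
#'
#' @param if_series an `if_series` from [extract_if()], or a bare channels
#'   x samples matrix.
#' @return Object of class `spatial_pattern_series`: `z` (samples x
#'   channels), logical `degenerate` per sample, `participant_id`, `group`,
#'   `fs_hz`, `channel_labels`.
#' @export
spatial_normalize <- function(if_series) {
  if (inherits(if_series, "if_series")) {
    m <- if_series$if_hz
    pid <- if_series$participant_id; grp <- if_series$group
    fs <- if_series$fs_hz; labs <- if_series$channel_labels
  } else {
    m <- if_series
    pid <- "p1"; grp <- NA_character_; fs <- NA_real_; labs <- rownames(m)
  }
  if (nrow(m) < 2) stop("spatial normalization needs >= 2 channels", call. = FALSE)
  D <- nrow(m)
  mu <- colMeans(m)
  centered <- sweep(m, 2, mu)
  # population-SD across the electrode dimension
  s <- sqrt(colSums(centered^2) / D)
  degenerate <- s < 1e-12
  s[degenerate] <- 1
  z <- t(sweep(centered, 2, s, "/"))
  z[degenerate, ] <- 0
  colnames(z) <- labs
  structure(list(z = z, degenerate = degenerate, participant_id = pid,
                 group = grp, fs_hz = fs, channel_labels = labs),
            class = "spatial_pattern_series")
}

#' @export
print.spatial_pattern_series <- function(x, ...) {
  cat(sprintf("<spatial_pattern_series> %s [%s]: %d samples x %d channels (%d degenerate)\n",
              x$participant_id, x$group, nrow(x$z), ncol(x$z), sum(x$degenerate)))
  invisible(x)
}

# stack participant series into one matrix, remembering sequence boundaries
pool_series <- function(series_list) {
  stopifnot(length(series_list) >= 1)
  zs <- lapply(series_list, function(s) s$z[!s$degenerate, , drop = FALSE])
  lens <- vapply(zs, nrow, 0L)
  if (any(lens == 0)) stop("a participant has no usable (non-degenerate) samples", call. = FALSE)
  list(X = do.call(rbind, zs),
       seq_len = lens,
       seq_start = cumsum(c(0L, lens[-length(lens)])),
       participant_id = vapply(series_list, function(s) s$participant_id, ""),
       group = vapply(series_list, function(s) s$group, ""))
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling proportional to squared distance from the nearest chosen center.
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (k in seq_len(K)[-1]) {
    probs <- d2 / sum(d2)
    centers[k, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ])^2))
  }
  centers
}

#' Group-level k-means initialization of state centroids
#'
#' Euclidean k-means on the pooled spatial patterns of all participants of
#' both groups, with k-means++ seeding and multiple restarts; the best run
#' (lowest total within-cluster sum of squares) provides the K centroids
#' used to initialize the HMM. Deterministic for a fixed seed. Centroids
#' are returned ordered by descending cluster size (ties: first-channel
#' value) so repeated runs agree.
#'
#' @param pooled pooled matrix from participant series (rows = samples,
#'   columns = channels), or a list of `spatial_pattern_series`.
#' @param K number of clusters (>= 1, <= number of rows).
#' @param seed integer seed.
#' @param nstart number of k-means++ restarts (default 20).
#' @param iter_max Lloyd iterations per restart.
#' @return K x channels centroid matrix.
#' @export
kmeans_init <- function(pooled, K, seed, nstart = 20, iter_max = 100) {
  if (is.list(pooled) && !is.matrix(pooled)) pooled <- pool_series(pooled)$X
  if (K > nrow(pooled))
    stop("K = ", K, " exceeds the ", nrow(pooled), " pooled samples", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (K == 1) {
    cen <- matrix(colMeans(pooled), 1)
    colnames(cen) <- colnames(pooled)
    return(cen)
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    cen0 <- kmeanspp_centers(pooled, K)
    km <- suppressWarnings(
      kmeans(pooled, centers = cen0, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  ord <- order(-best$size, -best$centers[, 1])
  cen <- best$centers[ord, , drop = FALSE]
  rownames(cen) <- NULL
  colnames(cen) <- colnames(pooled)
  cen
}

# log emission densities under diagonal Gaussians: n x K matrix
gaussian_logB <- function(X, means, vars) {
  K <- nrow(means); D <- ncol(means)
  A1 <- X^2 %*% t(1 / vars)
  A2 <- X %*% t(means / vars)
  cst <- rowSums(means^2 / vars) + rowSums(log(vars)) + D * log(2 * pi)
  -0.5 * (A1 - 2 * A2 + matrix(cst, nrow(X), K, byrow = TRUE))
}

#' Fit the shared microstate HMM by Baum-Welch EM
#'
#' Fits one first-order hidden Markov model with diagonal-covariance
#' Gaussian emissions to the pooled spatial-pattern sequences of all
#' participants, initialized at the k-means centroids. Sequences are kept
#' separate inside EM: the forward-backward recursions restart at every
#' participant boundary, so no transition is counted across participants.
#' The fitted model is shared by both groups; only the decoded sequences
#' are per-participant. After fitting, states are put in canonical order:
#' descending pooled Viterbi occupancy, ties broken by first-channel
#' centroid value.
#'
#' @param series_list list of `spatial_pattern_series` (one per
#'   participant).
#' @param init_centroids K x channels matrix from [kmeans_init()].
#' @param seed integer seed recorded in the fit log (the fit itself is
#'   deterministic given the initialization).
#' @param max_iter maximum EM iterations (default 200).
#' @param tol relative log-likelihood convergence tolerance (default 1e-4).
#' @param freeze_means if `TRUE`, emission means stay fixed at the k-means
#'   centroids and EM re-estimates only variances, transitions, and the
#'   initial distribution.
#' @param var_floor lower bound on emission variances.
#' @return Object of class `microstate_model`: `n_states`, `centroids`,
#'   `initial_distribution`, `transition_matrix`, `emission_means`,
#'   `emission_variances`, `channel_labels`, and `fit_log` (seed,
#'   iterations, log-likelihood trace, convergence flag).
#' @export
fit_hmm <- function(series_list, init_centroids, seed = 1, max_iter = 200,
                    tol = 1e-4, freeze_means = FALSE, var_floor = 1e-6) {
  pooled <- pool_series(series_list)
  X <- pooled$X
  K <- nrow(init_centroids)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (ncol(init_centroids) != ncol(X))
    stop("centroid dimension != channel count", call. = FALSE)
  D <- ncol(X)
  n_seq <- length(pooled$seq_len)

  means <- init_centroids
  vars <- matrix(1, K, D)
  pi0 <- rep(1 / K, K)
  A <- sticky_markov_spec(rep(0.9, K))$transition_matrix

  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logB <- gaussian_logB(X, means, vars)
    es <- hmm_estep_cpp(logB, pi0, A, pooled$seq_start, pooled$seq_len, X)
    if (!is.finite(es$loglik))
      stop("non-finite likelihood at EM iteration ", it, call. = FALSE)
    trace <- c(trace, es$loglik)
    if (it > 1) {
      rel <- (trace[it] - trace[it - 1]) / abs(trace[it - 1])
      if (abs(rel) < tol) { converged <- TRUE; break }
    }
    pi0 <- es$start_gamma / n_seq
    A <- es$trans_num / rowSums(es$trans_num)
    if (!freeze_means) means <- es$gx / es$gamma_sum
    vars <- pmax(es$gx2 / es$gamma_sum - (if (freeze_means) {
      2 * means * (es$gx / es$gamma_sum) - means^2
    } else means^2), var_floor)
  }

  model <- structure(
    list(n_states = K, centroids = init_centroids,
         initial_distribution = pi0, transition_matrix = A,
         emission_means = means, emission_variances = vars,
         channel_labels = colnames(X),
         fit_log = list(seed = seed, iterations = length(trace),
                        loglik_trace = trace, converged = converged,
                        freeze_means = freeze_means)),
    class = "microstate_model")
  canonical_order(model, series_list)
}

# reorder states by descending pooled Viterbi occupancy (ties: first-channel
# centroid value) and permute all parameter blocks accordingly
canonical_order <- function(model, series_list) {
  labels <- unlist(lapply(series_list, function(s) viterbi_labels(model, s$z[!s$degenerate, , drop = FALSE])))
  occ <- tabulate(labels, nbins = model$n_states) / length(labels)
  ord <- order(-occ, -model$emission_means[, 1])
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$initial_distribution <- model$initial_distribution[ord]
  model$transition_matrix <- model$transition_matrix[ord, ord, drop = FALSE]
  model$emission_means <- model$emission_means[ord, , drop = FALSE]
  model$emission_variances <- model$emission_variances[ord, , drop = FALSE]
  model$fit_log$canonical_occupancy <- occ[ord]
  model
}

viterbi_labels <- function(model, z) {
  logB <- gaussian_logB(z, model$emission_means, model$emission_variances)
  lp <- log(pmax(model$initial_distribution, 1e-300))
  lA <- log(pmax(model$transition_matrix, 1e-300))
  hmm_viterbi_cpp(logB, lp, lA)
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> K = %d states, %d channels; %d EM iterations (%s)\n",
              x$n_states, ncol(x$emission_means), x$fit_log$iterations,
              if (isTRUE(x$fit_log$converged)) "converged" else "max-iter"))
  cat("self-transitions:", paste(sprintf("%.3f", diag(x$transition_matrix)), collapse = " "), "\n")
  invisible(x)
}

#' Decode one participant's state sequence
#'
#' Viterbi most-probable path under the shared model. Degenerate
#' (zero-variance) samples are decoded too -- their flat pattern carries no
#' evidence and the path through them is set by the transition structure --
#' so the label sequence keeps the participant's full time base.
#'
#' @param model a `microstate_model`.
#' @param series one `spatial_pattern_series`.
#' @return Object of class `state_sequence`: integer `labels` (1..K),
#'   `participant_id`, `group`, `fs_hz`, `n_states`.
#' @export
decode <- function(model, series) {
  stopifnot(inherits(model, "microstate_model"),
            inherits(series, "spatial_pattern_series"))
  if (ncol(series$z) != ncol(model$emission_means))
    stop("channel count of series (", ncol(series$z),
         ") != model dimension (", ncol(model$emission_means), ")", call. = FALSE)
  structure(list(labels = viterbi_labels(model, series$z),
                 participant_id = series$participant_id, group = series$group,
                 fs_hz = series$fs_hz, n_states = model$n_states),
            class = "state_sequence")
}

#' AIC/BIC model-order selection curve
#'
#' Fits the full k-means + HMM pipeline for every candidate K and computes
#' AIC = 2p - 2 lnL and BIC = p ln(n) - 2 lnL with parameter count
#' p = (K - 1) + K(K - 1) + 2KD (initial distribution, transition matrix,
#' diagonal-Gaussian means and variances) and n the total pooled sample
#' count. The selected order is the elbow: the interior K maximizing the
#' discrete second difference of the criterion curve (BIC by default).
#'
#' @param series_list list of `spatial_pattern_series`.
#' @param k_range candidate state counts (>= 3 values for the elbow to be
#'   defined).
#' @param seed master seed (k-means seeding per K is derived from it).
#' @param criterion `"bic"` (default) or `"aic"` for the elbow.
#' @param ... passed on to [fit_hmm()].
#' @return list with `curve` (data.frame: K, loglik, n_params, aic, bic),
#'   `selected_k`, `criterion`, and `models` (one fitted model per K).
#' @export
model_selection <- function(series_list, k_range = 2:10, seed = 1,
                            criterion = c("bic", "aic"), ...) {
  criterion <- match.arg(criterion)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3)
    stop("elbow selection needs at least 3 candidate K values", call. = FALSE)
  pooled <- pool_series(series_list)
  n <- nrow(pooled$X); D <- ncol(pooled$X)
  rows <- list(); models <- list()
  for (K in k_range) {
    cen <- kmeans_init(pooled$X, K, seed = derive_seed(seed, K, 0L))
    m <- fit_hmm(series_list, cen, seed = seed, ...)
    ll <- tail(m$fit_log$loglik_trace, 1)
    p <- (K - 1) + K * (K - 1) + 2 * K * D
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = ll, n_params = p,
      aic = 2 * p - 2 * ll, bic = p * log(n) - 2 * ll)
    models[[as.character(K)]] <- m
  }
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  list(curve = curve, selected_k = elbow_k(curve$K, curve[[criterion]]),
       criterion = criterion, models = models)
}

#' Elbow of a criterion curve
#'
#' The candidate maximizing the discrete second difference
#' C(k-1) - 2 C(k) + C(k+1) over interior points -- the point where the
#' curve's slope flattens most sharply. Candidates must be consecutive for
#' the second difference to be meaningful; they are used as given.
#'
#' @param k candidate values (sorted).
#' @param crit criterion values at `k`.
#' @return the elbow `k`.
#' @export
elbow_k <- function(k, crit) {
  if (length(k) < 3) stop("elbow undefined for fewer than 3 candidates", call. = FALSE)
  i <- 2:(length(k) - 1)
  d2 <- crit[i - 1] - 2 * crit[i] + crit[i + 1]
  k[i][which.max(d2)]
}

#' Match estimated labels to ground truth by exhaustive permutation
#'
#' Finds the label permutation maximizing agreement between an estimated
#' and a reference state sequence (the assignment-problem optimum, found
#' exactly by exhaustive search over the K! permutations; K <= 8).
#'
#' @param est,truth integer label vectors of equal length.
#' @param K number of states.
#' @return list with `accuracy` (fraction matching under the best
#'   permutation), `permutation` (`perm[e]` = truth label for estimated
#'   label `e`), and `relabelled` (the permuted `est`).
#' @export
match_state_labels <- function(est, truth, K = max(est, truth)) {
  stopifnot(length(est) == length(truth))
  if (K > 8) stop("exhaustive matching supported for K <= 8", call. = FALSE)
  conf <- matrix(tabulate((truth - 1L) * K + est, nbins = K * K), K, K)
  perms <- permutations_of(K)
  scores <- vapply(seq_len(nrow(perms)), function(r)
    sum(conf[cbind(seq_len(K), perms[r, ])]), 0L)
  best <- unname(perms[which.max(scores), ])
  list(accuracy = max(scores) / length(est), permutation = best,
       relabelled = best[est])
}

permutations_of <- function(K) {
  if (K == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, 0, K)
  for (pos in seq_len(K)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], K,
                   sub[, seq(pos, K - 1)[seq_len(K - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}

#' Serialize / restore a microstate model as JSON
#'
#' @param model a `microstate_model`.
#' @param path JSON file path.
#' @return `write_model`: `path` invisibly; `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "microstate_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroids", "transition_matrix", "emission_means", "emission_variances"))
    m[[f]] <- as.matrix(m[[f]])
  colnames(m$emission_means) <- m$channel_labels
  structure(m, class = "microstate_model")
}
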