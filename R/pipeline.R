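#' Full-run configuration
#'
#' Assembles all pipeline options with defaults matching the reference
#' analysis setup: 4-13 Hz band, 5 s edge trim, 100 ms median filter,
#' 200 Hz / 60 s synthetic cohort, K selected over 2..8 by BIC elbow,
#' normality-gated tests with BH-FDR at q < 0.05.
#'
#' @param cohort a [cohort_spec()] to simulate, or `NULL` when
#'   `input_files` is given.
#' @param input_files optional character vector of EDF/CSV paths (with
#'   `groups` and, for CSV, `fs_hz`).
#' @param groups,fs_hz metadata for `input_files`.
#' @param band_low_hz,band_high_hz analysis band (Hz).
#' @param trim_s seconds trimmed from each end after filtering.
#' @param median_ms IF median-filter window (ms).
#' @param k fixed state count, or `NULL` to select over `k_range`.
#' @param k_range candidate K values for the elbow.
#' @param seed master seed for every stochastic stage.
#' @param contrast_group group treated as positive in comparisons.
#' @param test `"auto"`, `"welch_t"`, `"student_t"`, or `"mann_whitney_u"`.
#' @param alpha,fdr_q normality-gate level and FDR threshold.
#' @param out_dir optional directory for result artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(), input_files = NULL,
                       groups = NULL, fs_hz = NULL,
                       band_low_hz = 4, band_high_hz = 13, trim_s = 5,
                       median_ms = 100, k = NULL, k_range = 2:8, seed = 1,
                       contrast_group = NULL, test = "auto", alpha = 0.05,
                       fdr_q = 0.05, out_dir = NULL) {
  if (!is.null(input_files)) {
    missing <- input_files[!file.exists(input_files)]
    if (length(missing))
      stop("input files not found: ", paste(missing, collapse = ", "), call. = FALSE)
    if (is.null(groups) || length(groups) != length(input_files))
      stop("`groups` must label every input file", call. = FALSE)
  }
  structure(list(cohort = cohort, input_files = input_files, groups = groups,
                 fs_hz = fs_hz, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, trim_s = trim_s,
                 median_ms = median_ms, k = k, k_range = k_range,
                 seed = as.integer(seed), contrast_group = contrast_group,
                 test = test, alpha = alpha, fdr_q = fdr_q, out_dir = out_dir),
            class = "run_config")
}

#' Run the complete IF-microstate pipeline
#'
#' simulate (or read) -> band-pass -> trim -> IF extraction -> spatial
#' z-scoring -> pooled k-means + HMM fit (optionally with AIC/BIC model
#' selection) -> per-participant Viterbi decoding -> dynamics metrics ->
#' group statistics. Deterministic for a fixed config: rerunning yields
#' identical artifacts.
#'
#' @param config a [run_config()].
#' @return list of class `run_result`: `recordings` metadata, `series`
#'   (spatial pattern series), `model`, `selection` (model-selection curve
#'   or NULL), `sequences`, `metrics`, `tidy`, `comparisons`,
#'   `signed_map`, `config`, `warnings`.
#' @examples
#' \donttest{
#' cfg <- run_config(cohort = cohort_spec(n_per_group = c(a = 3, b = 3),
#'                                        duration_s = 12, seed = 2),
#'                   trim_s = 1, k = 5)
#' res <- run_full(cfg)
#' head(res$comparisons)
#' }
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  notes <- character(0)
  stage <- function(name, pid, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for participant '%s': %s",
                   name, pid, conditionMessage(e)), call. = FALSE))
  }

  # --- acquire recordings -------------------------------------------------
  if (is.null(config$input_files)) {
    cohort_data <- make_cohort(config$cohort)
    recs <- lapply(cohort_data, function(e) e$recording)
    truth <- lapply(cohort_data, function(e) e$ground_truth)
  } else {
    recs <- mapply(function(p, g)
      read_recording(p, fs_hz = config$fs_hz, group = g),
      config$input_files, config$groups, SIMPLIFY = FALSE)
    names(recs) <- vapply(recs, function(r) r$participant_id, "")
    truth <- NULL
  }

  # --- preprocess + IF + spatial normalization ---------------------------
  series <- lapply(recs, function(r) {
    stage("preprocess/extract", r$participant_id, {
      filt <- bandpass(r, config$band_low_hz, config$band_high_hz)
      filt <- trim_edges(filt, config$trim_s)
      spatial_normalize(extract_if(filt, window_ms = config$median_ms))
    })
  })
  n_degen <- sum(vapply(series, function(s) sum(s$degenerate), 0L))
  if (n_degen > 0)
    notes <- c(notes, sprintf("%d degenerate (zero-spatial-variance) samples excluded from fitting", n_degen))

  # --- state model --------------------------------------------------------
  selection <- NULL
  if (is.null(config$k)) {
    selection <- model_selection(series, k_range = config$k_range,
                                 seed = config$seed)
    model <- selection$models[[as.character(selection$selected_k)]]
    selection$models <- NULL   # keep the result bundle light
  } else {
    cen <- kmeans_init(series, config$k, seed = config$seed)
    model <- fit_hmm(series, cen, seed = config$seed)
  }
  if (!isTRUE(model$fit_log$converged))
    notes <- c(notes, "EM reached max iterations without meeting tolerance")

  # --- decode + metrics ---------------------------------------------------
  sequences <- lapply(series, function(s) stage("decode", s$participant_id,
                                                decode(model, s)))
  metrics <- lapply(sequences, dynamics_metrics)
  tidy <- tidy_metrics(metrics)

  # --- group statistics ---------------------------------------------------
  comparisons <- NULL; smap <- NULL
  if (length(unique(tidy$group[!is.na(tidy$group)])) == 2) {
    n_trans <- min(vapply(sequences, function(s) length(s$labels) - 1L, 0L))
    comparisons <- compare_metrics(
      tidy, contrast_group = config$contrast_group,
      parametric = if (config$test == "auto") "auto" else config$test,
      alpha = config$alpha, fdr_q = config$fdr_q, floor_total = n_trans)
    smap <- signed_significance_map(comparisons)
  }

  result <- structure(
    list(series = series, model = model, selection = selection,
         sequences = sequences, metrics = metrics, tidy = tidy,
         comparisons = comparisons, signed_map = smap,
         ground_truth = truth, config = config, warnings = notes),
    class = "run_result")
  if (!is.null(config$out_dir)) write_run_result(result, config$out_dir)
  result
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> %d participants, K = %d states\n",
              length(x$sequences), x$model$n_states))
  if (!is.null(x$selection))
    cat("model selection: elbow at K =", x$selection$selected_k, "\n")
  if (!is.null(x$comparisons))
    cat(sum(x$comparisons$significant), "of", nrow(x$comparisons),
        "comparisons significant at q <", x$config$fdr_q, "\n")
  for (w in x$warnings) cat("note:", w, "\n")
  invisible(x)
}

# write the artifact bundle: model JSON, sequences, metrics, comparisons
write_run_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_model(result$model, file.path(dir, "model.json"))
  seq_df <- do.call(rbind, lapply(result$sequences, function(s)
    data.frame(participant_id = s$participant_id, group = s$group,
               sample_index = seq_along(s$labels), label = s$labels)))
  write.csv(seq_df, file.path(dir, "state_sequences.csv"), row.names = FALSE)
  write.csv(result$tidy, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(result$comparisons))
    write.csv(result$comparisons, file.path(dir, "comparisons.csv"),
              row.names = FALSE)
  if (!is.null(result$selection))
    write.csv(result$selection$curve, file.path(dir, "model_selection.csv"),
              row.names = FALSE)
  cfg <- result$config
  cfg$cohort <- NULL
  jsonlite::write_json(list(seed = result$config$seed,
                            band = c(result$config$band_low_hz,
                                     result$config$band_high_hz),
                            trim_s = result$config$trim_s,
                            median_ms = result$config$median_ms,
                            warnings = result$warnings),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Export state centroid maps
#'
#' Per-state centroid table in the z-scored spatial space, plus (when
#' decoded sequences and series are supplied) the group-averaged observed
#' pattern of each state -- the group-level counterpart of the model
#' centroids.
#'
#' @param model a `microstate_model`.
#' @param series optional list of `spatial_pattern_series`.
#' @param sequences optional matching list of `state_sequence`.
#' @return data.frame: one row per (state, source) where source is
#'   `"centroid"` or `"group:<label>"`, channels as columns.
#' @export
export_state_maps <- function(model, series = NULL, sequences = NULL) {
  labs <- model$channel_labels
  out <- data.frame(state = seq_len(model$n_states), source = "centroid")
  out <- cbind(out, as.data.frame(model$emission_means))
  names(out)[-(1:2)] <- labs
  if (!is.null(series) && !is.null(sequences)) {
    groups <- unique(vapply(series, function(s) s$group, ""))
    for (g in groups) {
      idx <- which(vapply(series, function(s) identical(s$group, g), TRUE))
      Z <- do.call(rbind, lapply(idx, function(i) series[[i]]$z))
      L <- unlist(lapply(idx, function(i) sequences[[i]]$labels))
      gm <- t(vapply(seq_len(model$n_states), function(k)
        colMeans(Z[L == k, , drop = FALSE]), numeric(ncol(Z))))
      add <- data.frame(state = seq_len(model$n_states),
                        source = paste0("group:", g))
      add <- cbind(add, as.data.frame(gm))
      names(add)[-(1:2)] <- labs
      out <- rbind(out, add)
    }
  }
  rownames(out) <- NULL
  out
}
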