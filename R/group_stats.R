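#' Natural-log transform with an explicit zero floor
#'
#' Metrics such as transition probabilities can be exactly zero for a
#' participant; the log transform used before testing then needs a floor.
#' The default floor, when requested, is the smallest observable nonzero
#' probability 1/(total transition count), supplied by the caller as
#' `floor`. Without a floor, nonpositive values are an error naming the
#' offending entries.
#'
#' @param values numeric vector.
#' @param floor optional positive replacement for nonpositive values;
#'   floored entries are reported in the `"floored"` attribute.
#' @return log-transformed vector (attribute `floored`: indices replaced).
#' @export
log_transform <- function(values, floor = NULL) {
  bad <- which(values <= 0)
  if (length(bad) && is.null(floor))
    stop("nonpositive values at positions ", paste(bad, collapse = ", "),
         "; supply `floor` to proceed", call. = FALSE)
  if (length(bad)) values[bad] <- floor
  structure(log(values), floored = bad)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's Z_g1) and
#' kurtosis (Anscombe-Glynn's Z_g2) into K2 = Z_g1^2 + Z_g2^2, referred to
#' a chi-squared distribution with 2 df. Requires n >= 8 for the kurtosis
#' approximation to hold.
#'
#' @param x numeric sample (n >= 8, non-constant).
#' @return list with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test needs n >= 8", call. = FALSE)
  if (sd(x) < .Machine$double.eps)
    stop("sample is constant: skewness/kurtosis undefined", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transformation to normality
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  g2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eb2) / sqrt(Vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  list(statistic = K2, p_value = pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Normality gate for the two-sample test choice
#'
#' Runs the D'Agostino-Pearson test on each group; the parametric path is
#' taken only if both groups pass at `alpha`. Groups too small (n < 8) or
#' constant fall back to the nonparametric path with a warning.
#'
#' @param group_a,group_b numeric samples.
#' @param alpha normality significance level (default 0.05).
#' @return list with per-group `p` (NA if untestable), `parametric`
#'   (logical), `test_used` (`"welch_t"` candidate or `"mann_whitney_u"`).
#' @export
normality_gate <- function(group_a, group_b, alpha = 0.05) {
  test1 <- function(x) {
    if (length(x[is.finite(x)]) < 8 || sd(x) < .Machine$double.eps) {
      warning("group untestable for normality (n < 8 or constant); ",
              "falling back to Mann-Whitney", call. = FALSE)
      return(NA_real_)
    }
    dagostino_pearson(x)$p_value
  }
  pa <- test1(group_a); pb <- test1(group_b)
  parametric <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  list(p = c(a = pa, b = pb), parametric = parametric,
       test_used = if (parametric) "welch_t" else "mann_whitney_u")
}

#' Cohen's d from group summaries
#'
#' Pooled-SD standardized mean difference, (n-1)-weighted:
#' d = (m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)).
#'
#' @param m1,s1,n1 first group's mean, SD, size.
#' @param m2,s2,n2 second group's mean, SD, size.
#' @return Cohen's d (sign: first minus second group).
#' @export
cohens_d_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Two-sample comparison of one metric
#'
#' Welch's t-test (default parametric path; Student's available), or the
#' Mann-Whitney U test on the nonparametric path. The test runs on the
#' supplied values (typically log-transformed); Cohen's d is computed with
#' the pooled SD on the original scale passed via `raw_a`/`raw_b`
#' (defaults to the test values). Sign convention: first group minus
#' second.
#'
#' @param group_a,group_b samples entering the test.
#' @param test `"welch_t"`, `"student_t"`, or `"mann_whitney_u"`.
#' @param raw_a,raw_b original-scale samples for the effect size.
#' @return list with `p_value`, `cohens_d`, `direction` (sign of the
#'   group-a minus group-b mean difference on the original scale),
#'   `test_used`.
#' @export
compare_groups <- function(group_a, group_b,
                           test = c("welch_t", "student_t", "mann_whitney_u"),
                           raw_a = group_a, raw_b = group_b) {
  test <- match.arg(test)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  if (sd(group_a) < .Machine$double.eps && sd(group_b) < .Machine$double.eps) {
    if (mean(group_a) == mean(group_b))
      stop("zero variance in both groups and equal means: no comparison possible",
           call. = FALSE)
  }
  p <- switch(test,
    welch_t = t.test(group_a, group_b, var.equal = FALSE)$p.value,
    student_t = t.test(group_a, group_b, var.equal = TRUE)$p.value,
    mann_whitney_u = suppressWarnings(
      wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE)$p.value))
  d <- cohens_d_summary(mean(raw_a), sd(raw_a), length(raw_a),
                        mean(raw_b), sd(raw_b), length(raw_b))
  list(p_value = p, cohens_d = d,
       direction = sign(mean(raw_a) - mean(raw_b)), test_used = test)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()]; significance is
#' `q < fdr_q`.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return numeric vector of q-values, same order as input.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Signed significance scores
#'
#' sign(group difference) x (-log10 raw p): positive entries mean the
#' first (reference-contrast) group is larger. Used for transition-matrix
#' significance maps.
#'
#' @param p_raw raw p-values.
#' @param direction vector of signs (+1/-1/0).
#' @return numeric vector of signed scores.
#' @export
signed_significance <- function(p_raw, direction) {
  direction * (-log10(p_raw))
}

#' Group comparison over a tidy metrics table
#'
#' Runs the full statistical path for every (metric, state) and (metric,
#' from, to) cell of a [tidy_metrics()] table: natural-log transform
#' (zeros floored at 1/(total transition count) and flagged),
#' D'Agostino-Pearson normality gate, Welch/Student t or Mann-Whitney U,
#' then BH-FDR within each metric family (per-state metrics across the K
#' states of that metric; transition probabilities across the full K x K
#' set). Cohen's d and the group difference sign are reported on the
#' original metric scale as `contrast_group` minus the other group.
#'
#' @param tidy data.frame from [tidy_metrics()].
#' @param contrast_group group label whose excess is counted positive
#'   (default: last group level alphabetically, e.g. "younger" vs
#'   "middle_aged" gives middle-aged-positive with the default `"middle_aged"`
#'   ordering only if specified; pass explicitly for a fixed convention).
#' @param parametric `"auto"` (normality gate), `"welch_t"`,
#'   `"student_t"`, or `"mann_whitney_u"` to force a path.
#' @param log_before_test log-transform values before testing (default
#'   TRUE).
#' @param alpha normality-gate level.
#' @param fdr_q FDR significance threshold.
#' @param floor_total total transition count used for the zero floor
#'   1/floor_total; defaults to the largest per-cell sample count
#'   heuristic, see Details.
#' @return data.frame, one row per comparison: metric identifiers, group
#'   means/SDs, normality p per group, test used, `p_raw`, `q_fdr`,
#'   `significant`, `cohens_d`, `signed_score`, `n_floored`.
#' @export
compare_metrics <- function(tidy, contrast_group = NULL,
                            parametric = c("auto", "welch_t", "student_t",
                                           "mann_whitney_u"),
                            log_before_test = TRUE, alpha = 0.05,
                            fdr_q = 0.05, floor_total = NULL) {
  parametric <- match.arg(parametric)
  groups <- sort(unique(tidy$group))
  if (length(groups) != 2)
    stop("compare_metrics needs exactly 2 groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  if (is.null(contrast_group)) contrast_group <- groups[2]
  if (!contrast_group %in% groups)
    stop("`contrast_group` not among group labels", call. = FALSE)
  other <- setdiff(groups, contrast_group)

  key <- with(tidy, paste(metric, state, from_state, to_state, sep = "|"))
  cells <- unique(key)
  rows <- list()
  for (cell in cells) {
    sub <- tidy[key == cell, ]
    a <- sub$value[sub$group == contrast_group]   # contrast group first
    b <- sub$value[sub$group == other]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2) next
    # a cell constant and equal across both groups carries no evidence
    # (e.g. a transition observed by no participant, all floored): skip
    if (sd(a) < .Machine$double.eps && sd(b) < .Machine$double.eps &&
        mean(a) == mean(b)) next
    n_floored <- 0L
    ta <- a; tb <- b
    if (log_before_test) {
      fl <- if (!is.null(floor_total)) 1 / floor_total else {
        pos <- c(a, b)[c(a, b) > 0]
        if (length(pos)) min(pos) / 2 else 1e-12
      }
      ta <- log_transform(a, floor = fl)
      tb <- log_transform(b, floor = fl)
      n_floored <- length(attr(ta, "floored")) + length(attr(tb, "floored"))
    }
    gate_p <- c(NA_real_, NA_real_)
    test <- parametric
    if (parametric == "auto") {
      gate <- withCallingHandlers(normality_gate(ta, tb, alpha = alpha),
                                  warning = function(w) invokeRestart("muffleWarning"))
      gate_p <- gate$p
      test <- gate$test_used
    }
    cmp <- compare_groups(ta, tb, test = test, raw_a = a, raw_b = b)
    rows[[cell]] <- data.frame(
      metric = sub$metric[1], state = sub$state[1],
      from_state = sub$from_state[1], to_state = sub$to_state[1],
      mean_contrast = mean(a), sd_contrast = sd(a), n_contrast = length(a),
      mean_other = mean(b), sd_other = sd(b), n_other = length(b),
      normality_p_contrast = gate_p[1], normality_p_other = gate_p[2],
      test_used = cmp$test_used, p_raw = cmp$p_value,
      cohens_d = cmp$cohens_d, direction = cmp$direction,
      n_floored = n_floored)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # FDR families: each per-state metric across its states; transitions over K x K
  out$q_fdr <- NA_real_
  for (fam in unique(out$metric)) {
    i <- out$metric == fam
    out$q_fdr[i] <- fdr_correct(out$p_raw[i])
  }
  out$significant <- out$q_fdr < fdr_q
  out$signed_score <- signed_significance(out$p_raw, out$direction)
  attr(out, "contrast_group") <- contrast_group
  out
}

#' Signed significance map of transition comparisons
#'
#' Arranges the transition-probability rows of a [compare_metrics()] table
#' into a K x K matrix of signed scores (positive: contrast group higher),
#' with the q < threshold significance mask attached.
#'
#' @param comparisons data.frame from [compare_metrics()].
#' @return list with `scores` (K x K), `significant` (logical K x K),
#'   `contrast_group`.
#' @export
signed_significance_map <- function(comparisons) {
  tr <- comparisons[comparisons$metric == "transition_probability", ]
  if (!nrow(tr)) stop("no transition_probability rows in `comparisons`", call. = FALSE)
  K <- max(tr$from_state, tr$to_state)
  scores <- matrix(NA_real_, K, K)
  mask <- matrix(FALSE, K, K)
  scores[cbind(tr$from_state, tr$to_state)] <- tr$signed_score
  mask[cbind(tr$from_state, tr$to_state)] <- tr$significant
  dimnames(scores) <- dimnames(mask) <-
    list(paste0("state", 1:K), paste0("state", 1:K))
  list(scores = scores, significant = mask,
       contrast_group = attr(comparisons, "contrast_group"))
}

#' A-priori sample size for a two-sample t-test
#'
#' Smallest integer n per group such that the two-sided two-sample t-test
#' has power >= `power` at effect size d, using the exact noncentral-t
#' power function (df = 2n - 2, noncentrality d sqrt(n/2)).
#'
#' @param d assumed Cohen's d (nonzero).
#' @param alpha two-sided significance level.
#' @param power target power in (0, 1).
#' @return list with `n_per_group`, `n_total`, `achieved_power`.
#' @examples
#' power_analysis_n(d = 0.8)  # 26 per group, 52 total
#' @export
power_analysis_n <- function(d, alpha = 0.05, power = 0.80) {
  if (d == 0) stop("`d` must be nonzero", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("`alpha` and `power` must lie in (0, 1)", call. = FALSE)
  d <- abs(d)
  pow <- function(n) {
    df <- 2 * n - 2
    tc <- qt(1 - alpha / 2, df)
    ncp <- d * sqrt(n / 2)
    pt(-tc, df, ncp) + pt(tc, df, ncp, lower.tail = FALSE)
  }
  for (n in 2:1e6) {
    if (pow(n) >= power)
      return(list(n_per_group = n, n_total = 2L * n, achieved_power = pow(n)))
  }
  stop("target power unattainable below n = 1e6 per group", call. = FALSE)
}

#' Convert eta-squared to Cohen's d
#'
#' For a two-group contrast, d = 2 sqrt(eta2 / (1 - eta2)).
#'
#' @param eta2 proportion of variance explained, in \[0, 1).
#' @return Cohen's d.
#' @examples
#' eta_squared_to_d(0.2)  # 1.0
#' eta_squared_to_d(0.3)  # 1.309
#' @export
eta_squared_to_d <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) stop("`eta2` must lie in [0, 1)", call. = FALSE)
  2 * sqrt(eta2 / (1 - eta2))
}

#' Pearson chi-squared test for a 2 x 2 table
#'
#' Without continuity correction (df = 1), as used for checking the sex
#' distribution balance of a two-group cohort.
#'
#' @param table 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return list with `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_2x2(matrix(c(14, 7, 15, 11), 2))  # 0.396, p = 0.529
#' @export
chi_square_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == 2)) stop("`table` must be 2 x 2", call. = FALSE)
  if (any(tb < 0) || any(tb != round(tb)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0))
    stop("zero margin: chi-squared undefined", call. = FALSE)
  ct <- chisq.test(tb, correct = FALSE)
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}
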