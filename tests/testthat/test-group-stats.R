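test_that("log transform is exact, monotone, and floors flagged zeros", {
  expect_equal(log_transform(c(1, exp(1), exp(2))), c(0, 1, 2),
               ignore_attr = TRUE)
  expect_error(log_transform(c(1, 0, 2)), "position")
  lt <- log_transform(c(0.5, 0, 0.2), floor = 1e-4)
  expect_equal(as.numeric(lt), log(c(0.5, 1e-4, 0.2)))
  expect_identical(attr(lt, "floored"), 2L)
  set.seed(1)
  x <- sort(runif(50, 0.01, 10))
  expect_false(is.unsorted(log_transform(x)))
})

test_that("the omnibus normality statistic matches an external reference", {
  # frozen scipy.stats.normaltest values for three seeded samples
  set.seed(1); x <- rnorm(30)
  dp <- dagostino_pearson(x)
  expect_equal(dp$statistic, 4.1104148707, tolerance = 1e-7)
  expect_equal(dp$p_value, 0.1280662674, tolerance = 1e-7)
  set.seed(7); y <- exp(rnorm(25))
  dp2 <- dagostino_pearson(y)
  expect_equal(dp2$statistic, 16.4365367493, tolerance = 1e-7)
  expect_equal(dp2$p_value, 0.0002696816, tolerance = 1e-6)
  set.seed(3); z <- rt(18, df = 3)
  dp3 <- dagostino_pearson(z)
  expect_equal(dp3$statistic, 2.0266259341, tolerance = 1e-7)
  expect_equal(dp3$p_value, 0.3630143307, tolerance = 1e-7)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
  expect_error(dagostino_pearson(rep(1, 20)), "constant")
})

test_that("the normality gate has its nominal operating characteristics", {
  # both groups normal at the study sizes: parametric path in about
  # 0.95^2 = 90% of replicates
  set.seed(100)
  res <- replicate(1000,
    normality_gate(rnorm(29), rnorm(18))$parametric)
  expect_lt(abs(mean(res) - 0.95^2), 0.03)
  # a strongly lognormal group forces the nonparametric path
  set.seed(101)
  res2 <- replicate(200,
    normality_gate(exp(rnorm(29, sd = 1.5)), rnorm(18))$parametric)
  expect_lt(mean(res2), 0.05)
  # constant group: warning + nonparametric
  expect_warning(g <- normality_gate(rep(1, 10), rnorm(10)), "untestable")
  expect_identical(g$test_used, "mann_whitney_u")
})

test_that("effect sizes from summaries match the study-scale example", {
  # middle-aged-like 0.103 +/- 0.016 (n=18) vs younger-like 0.086 +/- 0.018
  # (n=29): pooled-SD d just under 1
  d <- cohens_d_summary(0.103, 0.016, 18, 0.086, 0.018, 29)
  expect_lt(abs(d - 0.98), 0.05)
  # d from raw samples with those exact moments equals the summary value
  force_moments <- function(n, m, s) {
    x <- rnorm(n); m + s * (x - mean(x)) / sd(x)
  }
  set.seed(12)
  a <- force_moments(18, 0.103, 0.016)
  b <- force_moments(29, 0.086, 0.018)
  cmp <- compare_groups(a, b, test = "welch_t")
  expect_equal(cmp$cohens_d, d, tolerance = 1e-9)
  expect_identical(cmp$direction, 1)
})

test_that("group comparisons are antisymmetric and null-consistent", {
  set.seed(21)
  a <- rnorm(20); b <- rnorm(25, mean = 0.5)
  f <- compare_groups(a, b, test = "welch_t")
  r <- compare_groups(b, a, test = "welch_t")
  expect_equal(f$p_value, r$p_value)
  expect_equal(f$cohens_d, -r$cohens_d)
  expect_identical(f$direction, -r$direction)
  # identical groups: Mann-Whitney with ties correction gives p = 1, d = 0
  x <- rep(c(1, 2, 3), 5)
  same <- compare_groups(x, x, test = "mann_whitney_u")
  expect_equal(same$p_value, 1)
  expect_equal(same$cohens_d, 0)
  # Welch and Student agree when sizes and variances are equal
  set.seed(22)
  g1 <- rnorm(30); g2 <- rnorm(30, 0.3)
  expect_equal(compare_groups(g1, g2, "welch_t")$p_value,
               compare_groups(g1, g2, "student_t")$p_value, tolerance = 1e-3)
})

test_that("BH adjustment matches hand-computed step-up values", {
  # all four pass their step-up thresholds 0.0125/0.025/0.0375/0.05
  q <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(q < 0.05))
  expect_equal(fdr_correct(0.037), 0.037)
  # ties: (0.04, 0.04, 0.04, 0.8) -> 0.0533... thrice, none significant
  q2 <- fdr_correct(c(0.04, 0.04, 0.04, 0.8))
  expect_equal(q2, c(0.16 / 3, 0.16 / 3, 0.16 / 3, 0.8))
  expect_false(any(q2 < 0.05))
  expect_error(fdr_correct(c(0.5, 1.2)), "outside")
})

test_that("BH agrees exactly with a brute-force step-up oracle", {
  set.seed(33)
  for (r in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)
    expect_equal(fdr_correct(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("signed significance scores encode direction and strength", {
  expect_equal(signed_significance(0.001, 1), 3)
  expect_equal(signed_significance(1, -1), 0)
  expect_equal(signed_significance(0.01, -1), -2)
})

test_that("a-priori power analysis reproduces the planning numbers", {
  p8 <- power_analysis_n(0.8, alpha = 0.05, power = 0.80)
  expect_identical(p8$n_per_group, 26L)
  expect_identical(p8$n_total, 52L)
  expect_gte(p8$achieved_power, 0.80)
  # one fewer participant per group must fall short of the target
  expect_lt(1 - pt(qt(0.975, 48), 48, 0.8 * sqrt(25 / 2)) +
              pt(-qt(0.975, 48), 48, 0.8 * sqrt(25 / 2)), 0.80)
  expect_identical(power_analysis_n(0.5)$n_per_group, 64L)
  expect_lt(power_analysis_n(1.6)$n_per_group, p8$n_per_group)
  expect_error(power_analysis_n(0), "nonzero")
})

test_that("eta-squared converts to d on the planning scale", {
  expect_equal(eta_squared_to_d(0.2), 1.0)
  expect_equal(round(eta_squared_to_d(0.3), 1), 1.3)
  expect_equal(eta_squared_to_d(0), 0)
  expect_error(eta_squared_to_d(1), "\\[0, 1\\)")
})

test_that("the 2x2 chi-squared matches the cohort sex-balance value", {
  tb <- matrix(c(14, 7, 15, 11), 2)  # males/females x group
  res <- chi_square_2x2(tb)
  expect_equal(res$statistic, 0.3959377, tolerance = 1e-6)
  expect_equal(res$p_value, 0.5291947, tolerance = 1e-6)
  expect_equal(res$df, 1)
  # independence and transposition symmetry
  expect_equal(chi_square_2x2(matrix(c(10, 5, 10, 5), 2))$statistic, 0)
  expect_equal(chi_square_2x2(t(tb))$statistic, res$statistic)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("compare_metrics corrects within families and maps transitions", {
  set.seed(55)
  mk_a <- sticky_markov_spec(rep(0.94, 3))
  mk_b <- sticky_markov_spec(c(0.97, 0.94, 0.91))  # strong contrast
  ms <- list()
  for (j in 1:12) {
    for (g in c("ga", "gb")) {
      lab <- sample_markov_chain(if (g == "ga") mk_a else mk_b, 6000,
                                 seed = j * 100 + (g == "gb"))
      m <- dynamics_metrics(lab, 200, 3)
      m$participant_id <- paste0(g, j); m$group <- g
      ms[[paste0(g, j)]] <- m
    }
  }
  cmp <- compare_metrics(tidy_metrics(ms), contrast_group = "gb",
                         floor_total = 5999)
  expect_true(all(cmp$q_fdr >= cmp$p_raw - 1e-12))
  # the contrast was built into state 1 (longer dwell in gb) and state 3
  dw1 <- cmp[cmp$metric == "mean_dwell_s" & cmp$state == 1, ]
  expect_true(dw1$significant)
  expect_gt(dw1$cohens_d, 0)
  dw3 <- cmp[cmp$metric == "mean_dwell_s" & cmp$state == 3, ]
  expect_lt(dw3$cohens_d, 0)
  smap <- signed_significance_map(cmp)
  expect_identical(dim(smap$scores), c(3L, 3L))
  tr11 <- cmp[cmp$metric == "transition_probability" &
                cmp$from_state == 1 & cmp$to_state == 1, ]
  expect_equal(smap$scores[1, 1], tr11$signed_score)
  expect_identical(smap$significant[1, 1], tr11$significant)
  expect_gt(smap$scores[1, 1], 0)  # gb stickier in state 1
})

test_that("a 0.01 self-transition dwell contrast is detected at n = 26 per group", {
  # group A self-transition 0.94 vs group B 0.95 for state 1: the dwell
  # difference (83 vs 100 ms at 200 Hz) should reach q < 0.05 in the
  # majority of replicates (label-sequence level; the contrast lives
  # entirely in the Markov dynamics)
  K <- 5
  mk_a <- sticky_markov_spec(rep(0.94, K))
  mk_b <- sticky_markov_spec(c(0.95, rep(0.94, K - 1)))
  hits <- logical(5)
  for (r in 1:5) {
    metrics <- list()
    for (g in 1:2) {
      for (j in 1:26) {
        lab <- sample_markov_chain(if (g == 1) mk_a else mk_b, 10000,
                                   seed = derive_seed(4000 + r, g, j))
        m <- dynamics_metrics(lab, 200, K)
        m$participant_id <- sprintf("g%d_%02d", g, j)
        m$group <- c("ga", "gb")[g]
        metrics[[m$participant_id]] <- m
      }
    }
    cmp <- compare_metrics(tidy_metrics(metrics), contrast_group = "gb",
                           floor_total = 9999)
    hits[r] <- cmp$significant[cmp$metric == "mean_dwell_s" & cmp$state == 1]
  }
  expect_gte(sum(hits), 3)
})
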