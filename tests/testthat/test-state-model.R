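test_that("spatial normalization centers and scales each time point", {
  # one time point (8, 10, 12) across three channels, population SD
  s <- spatial_normalize(matrix(c(8, 10, 12), 3, 1,
                                dimnames = list(c("a", "b", "c"), NULL)))
  expect_equal(s$z[1, ], c(a = -1.224745, b = 0, c = 1.224745), tolerance = 1e-6)
  expect_false(s$degenerate[1])
  # constant time point is degenerate, not fatal
  s2 <- spatial_normalize(matrix(c(10, 10, 10, 8, 10, 12), 3, 2))
  expect_identical(s2$degenerate, c(TRUE, FALSE))
  expect_equal(s2$z[1, ], c(0, 0, 0))
  # invariant: row means vanish, population SD is 1
  set.seed(5)
  s3 <- spatial_normalize(matrix(rnorm(16 * 50), 16, 50))
  expect_lt(max(abs(rowMeans(s3$z))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(s3$z^2) / 16) - 1)), 1e-9)
})

test_that("k-means initialization finds separated clouds exactly", {
  set.seed(2)
  a <- matrix(rnorm(200, mean = 0, sd = 0.1), 100, 2)
  b <- matrix(rnorm(160, mean = 10, sd = 0.1), 80, 2)
  X <- rbind(a, b)
  cen <- kmeans_init(X, 2, seed = 1)
  # ordered by descending cluster size: a's mean first
  expect_equal(cen[1, ], colMeans(a), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cen[2, ], colMeans(b), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(kmeans_init(X, 1, seed = 1)[1, ], colMeans(X),
               ignore_attr = TRUE)
  expect_identical(kmeans_init(X, 2, seed = 7), kmeans_init(X, 2, seed = 7))
  expect_error(kmeans_init(X[1:3, ], 5, seed = 1), "exceeds")
})

test_that("EM recovers the parameters of an exactly-Gaussian HMM", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  mu <- rbind(c(-1, 0), c(1, 0.5))
  n <- 1e5
  z <- sample_markov_chain(markov_spec(A), n, seed = 3)
  set.seed(9)
  X <- mu[z, ] + matrix(rnorm(2 * n, sd = 0.5), n, 2)
  colnames(X) <- c("c1", "c2")
  m <- fit_hmm(list(as_sps(X)), mu, seed = 4, tol = 1e-7, max_iter = 500)
  ord <- order(m$emission_means[, 1])
  expect_lt(max(abs(m$transition_matrix[ord, ord] - A)), 0.02)
  expect_lt(max(abs(m$emission_means[ord, ] - mu)), 0.02)
  # EM contract: monotone log-likelihood, stochastic rows
  tr <- m$fit_log$loglik_trace
  expect_true(all(diff(tr) > -1e-6 * abs(tr[-1])))
  expect_equal(rowSums(m$transition_matrix), c(1, 1), tolerance = 1e-9)
})

test_that("Baum-Welch agrees with an independently fitted reference", {
  # 3000-sample 2-state fixture; reference values computed once with
  # hmmlearn's GaussianHMM (diagonal covariance) from the same
  # initialization and frozen here
  A0 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  mu <- rbind(c(-1, 0), c(1, 0.5))
  z <- sample_markov_chain(markov_spec(A0), 3000, seed = 3)
  set.seed(31)
  X <- mu[z, ] + matrix(rnorm(2 * 3000, sd = 0.5), 3000, 2)
  colnames(X) <- c("c1", "c2")
  m <- fit_hmm(list(as_sps(X)), mu, seed = 1, tol = 1e-9, max_iter = 1000)
  ord <- order(m$emission_means[, 1])
  ref_A <- matrix(c(0.90057832, 0.09942168, 0.17664076, 0.82335924), 2,
                  byrow = TRUE)
  ref_means <- rbind(c(-0.99816681, -0.007724), c(1.00997869, 0.46958374))
  expect_lt(max(abs(m$transition_matrix[ord, ord] - ref_A)), 0.005)
  expect_lt(max(abs(m$emission_means[ord, ] - ref_means)), 0.005)
  expect_lt(abs(tail(m$fit_log$loglik_trace, 1) - (-5391.8166)), 0.05)
})

test_that("a K=2 fit on unimodal noise still satisfies the model contract", {
  set.seed(6)
  X <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("c1", "c2")))
  cen <- kmeans_init(X, 2, seed = 2)
  m <- fit_hmm(list(as_sps(X)), cen, seed = 2)
  expect_equal(rowSums(m$transition_matrix), c(1, 1), tolerance = 1e-9)
  expect_true(all(m$emission_variances > 0))
})

test_that("decoding is exact in the small-variance limit and deterministic", {
  A <- matrix(c(0.95, 0.05, 0.1, 0.9), 2, byrow = TRUE)
  mu <- rbind(c(-1, -1), c(1, 1))
  path <- sample_markov_chain(markov_spec(A), 2000, seed = 12)
  set.seed(13)
  X <- mu[path, ] + matrix(rnorm(4000, sd = 0.01), 2000, 2)
  colnames(X) <- c("c1", "c2")
  model <- structure(
    list(n_states = 2L, centroids = mu, initial_distribution = c(0.5, 0.5),
         transition_matrix = A, emission_means = mu,
         emission_variances = matrix(0.01^2, 2, 2),
         channel_labels = c("c1", "c2"),
         fit_log = list(seed = 1, iterations = 0, loglik_trace = numeric(0),
                        converged = TRUE)),
    class = "microstate_model")
  s <- as_sps(X)
  dec <- decode(model, s)
  expect_identical(dec$labels, path)
  expect_identical(decode(model, s)$labels, dec$labels)
  # dimension mismatch is caught
  s3 <- as_sps(cbind(X, 0))
  expect_error(decode(model, s3), "channel count")
})

test_that("state identities are stable across refits with different seeds", {
  A <- sticky_markov_spec(rep(0.9, 3))
  mu <- rbind(c(-2, 0), c(2, 0), c(0, 2))
  path <- sample_markov_chain(A, 4000, seed = 21)
  set.seed(22)
  X <- mu[path, ] + matrix(rnorm(8000, sd = 0.3), 4000, 2)
  colnames(X) <- c("c1", "c2")
  fit1 <- fit_hmm(list(as_sps(X)), kmeans_init(X, 3, seed = 1), seed = 1)
  fit2 <- fit_hmm(list(as_sps(X)), kmeans_init(X, 3, seed = 99), seed = 99)
  expect_lt(max(abs(fit1$emission_means - fit2$emission_means)), 0.05)
  expect_lt(max(abs(fit1$transition_matrix - fit2$transition_matrix)), 0.02)
})

test_that("information criteria use the stated parameter count and elbow rule", {
  # p = (K-1) + K(K-1) + 2 K D
  A <- sticky_markov_spec(rep(0.9, 2))
  path <- sample_markov_chain(A, 600, seed = 2)
  mu <- rbind(c(-1, 0), c(1, 0))
  set.seed(3)
  X <- mu[path, ] + matrix(rnorm(1200, sd = 0.4), 600, 2)
  colnames(X) <- c("c1", "c2")
  sel <- model_selection(list(as_sps(X)), k_range = 2:4, seed = 1,
                         max_iter = 50)
  expect_identical(sel$curve$n_params,
                   c(2 - 1 + 2 * 1 + 2 * 2 * 2, 3 - 1 + 3 * 2 + 2 * 3 * 2,
                     4 - 1 + 4 * 3 + 2 * 4 * 2))
  # K = 5, D = 16 parameter count used for the EEG montage
  expect_identical((5 - 1) + 5 * (5 - 1) + 2 * 5 * 16, 184)
  # elbow = maximal discrete second difference
  expect_identical(elbow_k(2:7, c(100, 60, 30, 20, 15, 12)), 4L)
  expect_error(elbow_k(2:3, c(10, 5)), "3 candidates")
})

test_that("label matching finds the optimal permutation", {
  est <- c(1L, 1L, 2L, 2L, 3L)
  truth <- c(2L, 2L, 1L, 1L, 3L)
  m <- match_state_labels(est, truth, 3)
  expect_identical(m$permutation, c(2L, 1L, 3L))
  expect_identical(m$accuracy, 1)
  expect_identical(m$relabelled, truth)
  m2 <- match_state_labels(c(1L, 1L, 1L, 2L), c(2L, 2L, 1L, 1L), 2)
  expect_identical(m2$accuracy, 0.75)
})

test_that("models survive a JSON round trip", {
  path <- withr::local_tempfile(fileext = ".json")
  mu <- rbind(c(-1, 0), c(1, 0.5))
  z <- sample_markov_chain(sticky_markov_spec(0.9, 2), 500, seed = 3)
  set.seed(8)
  X <- mu[z, ] + matrix(rnorm(1000, sd = 0.5), 500, 2)
  colnames(X) <- c("c1", "c2")
  m <- fit_hmm(list(as_sps(X)), mu, seed = 1)
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$transition_matrix, m$transition_matrix,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$emission_means, m$emission_means, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$n_states, m$n_states)
})
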