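test_that("K = 1 fit reproduces the closed-form Gaussian solution", {
  set.seed(4)
  x <- rnorm(400, 0.3, 0.05)
  fit <- fit_hmm(x, 1)
  m <- mean(x); v <- mean((x - m)^2)  # ML variance
  expect_equal(fit$means, m, tolerance = 1e-6)
  expect_equal(fit$variances, v, tolerance = 1e-4)
  expect_equal(fit$log_likelihood,
               sum(dnorm(x, fit$means, sqrt(fit$variances), log = TRUE)),
               tolerance = 1e-6)
})

test_that("noiseless alternating two-level trace is fit exactly", {
  x <- rep(c(0.2, 0.45), 50)
  fit <- fit_hmm(x, 2)
  expect_equal(fit$means, c(0.2, 0.45), tolerance = 1e-6)
  expect_equal(fit$variances, c(1e-6, 1e-6))  # variance floor
})

test_that("simulated 2-state trace parameters are recovered", {
  cfg <- sim_config(list(sim_state("C", 0.196, 0.05, 0.3), sim_state("O", 0.448, 0.05, 0.3)),
                    mechanism = c("C", "O"), type = "reversible",
                    length_frames = 1000L)
  ds <- make_dataset(cfg)
  fit <- fit_hmm(ds[[1]]$trajectory$e_star, 2)
  expect_lt(max(abs(fit$means - c(0.196, 0.448))), 0.02)
  expect_true(all(abs(rowSums(fit$transition_matrix) - 1) < 1e-9))
})

test_that("EM log-likelihood is monotonically non-decreasing", {
  set.seed(6)
  for (i in 1:10) {
    x <- c(rnorm(60, 0.2, 0.05), rnorm(60, 0.45, 0.05))[sample(120)]
    fit <- fit_hmm(x, sample(2:3, 1), n_restarts = 2, seed = i)
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
  }
})

test_that("viterbi matches brute-force enumeration on small instances", {
  set.seed(7)
  for (i in 1:40) {
    K <- sample(2:3, 1)
    T <- sample(4:8, 1)
    h <- random_hmm(K)
    x <- runif(T)
    oracle <- brute_viterbi(x, h$means, h$vars, h$trans, h$init)
    if (!oracle$unique) next
    fit <- manual_fit(h$means, h$vars, h$trans, h$init)
    expect_equal(viterbi(fit, x)$states, oracle$path)
  }
})

test_that("viterbi ties break toward the lower state index", {
  fit <- manual_fit(c(0.2, 0.4), c(0.0025, 0.0025),
                    matrix(0.5, 2, 2), c(0.5, 0.5))
  # frames exactly midway between the means: everything ties
  v <- viterbi(fit, c(0.3, 0.3))
  expect_equal(v$states, c(1L, 1L))
})

test_that("canonical fit is invariant to the restart seed on separable data", {
  cfg <- sim_config(list(sim_state("C", 0.2, 0.04, 0.3), sim_state("O", 0.45, 0.04, 0.3)),
                    mechanism = c("C", "O"), type = "reversible", length_frames = 600L)
  x <- make_dataset(cfg)[[1]]$trajectory$e_star
  f1 <- fit_hmm(x, 2, seed = 1)
  f2 <- fit_hmm(x, 2, seed = 1234)
  expect_equal(f1$means, f2$means, tolerance = 1e-5)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-6)
})

test_that("AIC identity holds with the documented parameter count", {
  set.seed(8)
  x <- c(rnorm(80, 0.2, 0.05), rnorm(80, 0.45, 0.05))
  for (k in 1:3) {
    fit <- fit_hmm(x, k)
    expect_equal(fit$n_free_params, k^2 + 2 * k - 1)
    expect_equal(fit$aic, 2 * fit$n_free_params - 2 * fit$log_likelihood)
  }
  # chain + fixed-variance counting: K-1 transitions + K means
  fitc <- fit_hmm(x, 2, topology = "chain", var_mode = "fixed")
  expect_equal(fitc$n_free_params, 3L)
})

test_that("fit_hmm rejects degenerate inputs", {
  expect_error(fit_hmm(c(0.2, 0.3, 0.4), 2), "fewer than 2k")
  expect_error(fit_hmm(rep(0.3, 50), 2), "degenerate")
  expect_error(fit_hmm(runif(50), 4), "k must be")
})

test_that("mechanism selection enforces the AIC rule regardless of likelihood", {
  x <- c(rnorm(50, 0.2, 0.05), rnorm(150, 0.45, 0.05))
  fit2 <- fit_hmm(x, 2, topology = "chain", var_mode = "fixed")
  fit3 <- fit_hmm(x, 3, topology = "chain", var_mode = "fixed")
  p2 <- filter_transitions(viterbi(fit2, x), x, 2)
  p3 <- filter_transitions(viterbi(fit3, x), x, 2)
  fit3_bad <- fit3
  fit3_bad$log_likelihood <- fit2$log_likelihood + 100  # force criterion (a)
  fit3_bad$aic <- fit2$aic + 1                          # but fail criterion (b)
  expect_equal(select_mechanism(fit2, fit3_bad, p2, p3), "two_state")
})
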