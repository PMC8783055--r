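test_that("allan deviation matches closed forms", {
  expect_equal(allan_deviation(rep(0.4, 100)), 0)
  d <- 0.07
  x <- rep(c(0.3 + d, 0.3 - d), 50)
  expect_equal(allan_deviation(x), d * sqrt(2))
  expect_error(allan_deviation(0.3), ">= 2 defined")
})

test_that("allan deviation estimates sigma on white noise, scaled by sqrt(m)", {
  set.seed(9)
  sigma <- 0.06
  x <- rnorm(10000, 0.4, sigma)
  se <- sigma / sqrt(2 * 10000)
  expect_lt(abs(allan_deviation(x) - sigma), 3 * se)
  expect_lt(abs(allan_deviation(x, m = 2) - sigma / sqrt(2)), 6 * se)
  expect_lt(abs(allan_deviation(x, robust = TRUE) - sigma), 5 * se)
})

test_that("filter accepts and rejects steps by the multiplier rule", {
  # two levels 0.25 apart, allan supplied as 0.05, multiplier 3 -> thr 0.15
  p <- manual_path(c(rep(1, 10), rep(2, 10)), c(0.2, 0.45))
  f <- filter_transitions(p, runif(20), 3, allan = 0.05)
  expect_equal(nrow(f$accepted_transitions), 1)
  expect_equal(f$accepted_transitions$frame, 10)
  expect_equal(f$accepted_transitions$delta_e, 0.25)

  # step of 0.10 with the same settings is rejected and the dwells merged
  p2 <- manual_path(c(rep(1, 10), rep(2, 4), rep(1, 10)), c(0.30, 0.40))
  f2 <- filter_transitions(p2, runif(24), 3, allan = 0.05)
  expect_equal(nrow(f2$accepted_transitions), 0)
  expect_equal(f2$states, rep(1L, 24))
})

test_that("rejected short dwell merges into the nearest-level neighbour", {
  # middle dwell shorter; levels: 0.2, 0.28, 0.45 -> nearer neighbour is state 1
  p <- manual_path(c(rep(1, 10), rep(2, 3), rep(3, 10)), c(0.2, 0.28, 0.45))
  f <- filter_transitions(p, runif(23), 3, allan = 0.05)
  expect_equal(f$states, c(rep(1L, 13), rep(3L, 10)))
  expect_equal(nrow(f$accepted_transitions), 1)
})

test_that("filtering is idempotent and monotone in the multiplier", {
  ds <- simulate_dynamic_dataset(6, c(120, 160), seed = 13)
  for (it in ds) {
    x <- it$trajectory$e_star
    fit <- fit_hmm(x, 2, 3, 1)
    v <- viterbi(fit, x)
    counts <- integer(0)
    for (mult in c(1, 2, 3, 4)) {
      f <- filter_transitions(v, x, mult)
      counts <- c(counts, nrow(f$accepted_transitions))
      f2 <- filter_transitions(f, x, mult)
      expect_identical(f2$states, f$states)
      expect_identical(f2$accepted_transitions, f$accepted_transitions)
    }
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("noise-only traces yield no accepted transitions", {
  set.seed(14)
  clean <- 0L
  n_trials <- 200L
  for (i in seq_len(n_trials)) {
    x <- rnorm(200, 0.45, 0.05)
    fit <- fit_hmm(x, 2, n_restarts = 2, seed = i)
    f <- filter_transitions(viterbi(fit, x), x, 3)
    if (nrow(f$accepted_transitions) == 0) clean <- clean + 1L
  }
  expect_gte(clean / n_trials, 0.95)
})

test_that("dwell extraction honours censoring flags and conserves frames", {
  p <- manual_path(c(rep(1, 10), rep(2, 5), rep(1, 7)), c(0.2, 0.45))
  dw <- extract_dwells(p, drop_censored = TRUE)
  expect_equal(nrow(dw), 1)
  expect_equal(dw$state, 2L)
  expect_equal(dw$length_frames, 5L)
  expect_equal(dw$length_s, 5 * 0.02)

  expect_equal(nrow(extract_dwells(manual_path(rep(1, 30), 0.2), drop_censored = TRUE)), 0)

  # conservation across simulated trajectories
  ds <- simulate_dynamic_dataset(10, c(100, 200), seed = 15)
  for (it in ds) {
    x <- it$trajectory$e_star
    f <- filter_transitions(viterbi(fit_hmm(x, 2, 2, 1), x), x, 3)
    dw <- extract_dwells(f)
    expect_equal(sum(dw$length_frames), length(x))
    expect_true(dw$left_censored[1])
    expect_true(dw$right_censored[nrow(dw)])
  }
})
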