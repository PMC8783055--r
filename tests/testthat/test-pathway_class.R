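filtered_stub <- function(n_acc) {
  structure(list(states = rep(1L, 10), state_means = 0.4,
                 accepted_transitions = data.frame(frame = seq_len(n_acc),
                                                   from = rep(1L, n_acc),
                                                   to = rep(2L, n_acc),
                                                   delta_e = rep(0.2, n_acc)),
                 allan_dev = 0.05, multiplier = 3),
            class = "filtered_path")
}

test_that("dynamics rule: > 2 accepted transitions", {
  expect_equal(classify_dynamics(filtered_stub(0)), "static")
  expect_equal(classify_dynamics(filtered_stub(2)), "static")
  expect_equal(classify_dynamics(filtered_stub(3)), "dynamic")
})

test_that("static single-state simulations never classify as dynamic", {
  cfg <- sim_config(list(sim_state("RP_O", 0.462, 0.06, 1)), mechanism = "RP_O",
                    length_frames = c(150L, 300L), n_trajectories = 40L, seed = 31L)
  ds <- make_dataset(cfg)
  cls <- vapply(seq_along(ds), function(t) {
    analyze_dynamics(ds[[t]]$trajectory, seed = t)$class
  }, "")
  expect_equal(sum(cls == "dynamic"), 0)
})

test_that("mechanism classification distinguishes none / direct / via_RPi", {
  set.seed(32)
  # stays in the closed state: no opening
  x_none <- rnorm(150, 0.2, 0.05)
  tr_none <- trajectory(0.02, e_star = x_none)
  r <- analyze_opening(tr_none, seed = 1)
  cls <- classify_mechanism(tr_none, r$fit2, r$fit3, r$path2, r$path3)
  expect_equal(cls$mechanism, "none")
  expect_true(is.na(cls$rp_c_waiting_s))

  # direct opening trajectories
  ds_direct <- simulate_opening_dataset(30, rpi_frames = NULL, seed = 33)
  mech <- vapply(seq_along(ds_direct), function(t) {
    tr <- ds_direct[[t]]$trajectory
    r <- analyze_opening(tr, seed = t)
    classify_mechanism(tr, r$fit2, r$fit3, r$path2, r$path3)$mechanism
  }, "")
  expect_gte(mean(mech == "direct"), 0.8)

  # 8-frame intermediate dwells are mostly recognised
  ds_rpi <- simulate_opening_dataset(30, rpi_frames = 8, seed = 34)
  mech2 <- vapply(seq_along(ds_rpi), function(t) {
    tr <- ds_rpi[[t]]$trajectory
    r <- analyze_opening(tr, seed = t)
    classify_mechanism(tr, r$fit2, r$fit3, r$path2, r$path3)$mechanism
  }, "")
  expect_gte(mean(mech2 == "via_RPi"), 0.6)
})

test_that("closed-complex waiting time spans binding to the opening step", {
  set.seed(35)
  x <- c(rnorm(50, 0.196, 0.04), rnorm(150, 0.448, 0.04))
  tr <- trajectory(0.02, e_star = x)
  r <- analyze_opening(tr, seed = 2)
  cls <- classify_mechanism(tr, r$fit2, r$fit3, r$path2, r$path3)
  expect_equal(cls$mechanism, "direct")
  expect_equal(cls$rp_c_waiting_s, 1.0, tolerance = 0.06)
})

test_that("Clopper-Pearson interval matches beta quantiles and boundaries", {
  ci0 <- exact_binomial_ci(0, 10)
  expect_equal(ci0$lo, 0)
  ci1 <- exact_binomial_ci(10, 10)
  expect_equal(ci1$hi, 1)
  expect_error(exact_binomial_ci(5, 0), "trials")
  expect_error(exact_binomial_ci(11, 10), "successes")

  ci <- exact_binomial_ci(107, 147)
  expect_equal(ci$point, 107 / 147)
  expect_equal(round(ci$point, 3), 0.728)
  # oracle: direct beta-quantile evaluation
  expect_equal(ci$lo, qbeta(0.025, 107, 41))
  expect_equal(ci$hi, qbeta(0.975, 108, 40))
  expect_equal(round(c(ci$lo, ci$hi), 2), c(0.65, 0.80))
  expect_true(ci$lo <= ci$point && ci$point <= ci$hi)
})

test_that("Clopper-Pearson coverage is at least nominal", {
  set.seed(36)
  for (p in c(0.1, 0.3, 0.7)) {
    for (n in c(40, 150)) {
      s <- rbinom(10000, n, p)
      lo <- ifelse(s == 0, 0, qbeta(0.025, s, n - s + 1))
      hi <- ifelse(s == n, 1, qbeta(0.975, s + 1, n - s))
      expect_gte(mean(lo <= p & p <= hi), 0.95)
    }
  }
})

test_that("fraction bookkeeping: static + dynamic = classified total", {
  expect_equal(exact_binomial_ci(107, 147)$point + exact_binomial_ci(40, 147)$point, 1)
})

test_that("two-sample comparison reports pooled and Welch variants", {
  r <- compare_fractions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$pooled$t, 0)
  expect_equal(r$pooled$p_value, 1)

  r2 <- compare_fractions(c(1, 2, 3), c(101, 102, 103))
  expect_lt(r2$pooled$p_value, 0.001)

  # balanced groups: pooled and Welch statistics coincide (closed-form identity)
  set.seed(37)
  a <- rnorm(6); b <- rnorm(6)
  r3 <- compare_fractions(a, b)
  expect_equal(r3$pooled$t, r3$welch$t, tolerance = 1e-12)

  expect_error(compare_fractions(1, c(1, 2)), ">= 2 replicates")
})
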