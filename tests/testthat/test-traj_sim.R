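test_that("exit probability matches the closed form", {
  expect_equal(exit_probability(0.56, 0.02), 1 - exp(-0.02 / 0.56))
  expect_equal(round(exit_probability(0.56, 0.02), 4), 0.0351)
})

test_that("config validation catches bad inputs", {
  st <- sim_preset("three-state")
  expect_error(sim_config(st, mechanism = c("RP_C", "nope")), "unknown state")
  expect_error(sim_config(st, frame_time = 0), "frame_time")
  expect_error(sim_config(st, length_frames = 1), "length_frames")
  expect_error(sim_state("A", 1.5, 0.05), "mean_estar")
  expect_error(sim_state("A", 0.5, 0.05, mean_lifetime = -1), "mean_lifetime")
  # chain needs lifetimes on all non-terminal states
  expect_error(sim_config(list(sim_state("A", 0.2, 0.05), sim_state("B", 0.4, 0.05)),
                          mechanism = c("A", "B")), "mean_lifetime")
})

test_that("one-state mechanism yields a constant path", {
  cfg <- sim_config(list(sim_state("S", 0.4, 0.05, 1)), mechanism = "S",
                    length_frames = 50L)
  p <- simulate_path(cfg, 1)
  expect_equal(p$states, rep(1L, 50))
})

test_that("dwell lengths are geometric with the analytic mean", {
  cfg <- sim_config(list(sim_state("A", 0.2, 0.05, 0.5), sim_state("B", 0.45, 0.05, 0.5)),
                    mechanism = c("A", "B"), type = "reversible",
                    length_frames = 60000L)
  p <- simulate_path(cfg, 7)
  dw <- extract_dwells(p, drop_censored = TRUE)
  k <- dw$length_frames
  pr <- exit_probability(0.5, 0.02)
  mean_true <- 1 / pr
  se <- sqrt((1 - pr) / pr^2) / sqrt(length(k))
  expect_lt(abs(mean(k) - mean_true), 3 * se)

  # chi-square goodness of fit against the geometric law, alpha = 0.01
  expect_gt(length(k), 2000)
  cut <- 8L
  obs <- tabulate(pmin(k, cut), nbins = cut)
  pgeo <- dgeom(0:(cut - 2), pr)
  probs <- c(pgeo, 1 - sum(pgeo))
  gof <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("reversible chain occupancies converge to the analytic values", {
  tau <- c(0.085, 0.56)
  cfg <- sim_config(list(sim_state("RP_ISO", 0.279, 0.06, tau[1]),
                         sim_state("RP_O", 0.462, 0.06, tau[2])),
                    mechanism = c("RP_ISO", "RP_O"), type = "reversible",
                    length_frames = 40000L)
  p <- simulate_path(cfg, 3)
  occ <- mean(p$states == 2L)
  pi2 <- tau[2] / sum(tau)  # alternating renewal occupancy
  n_cycles <- sum(diff(p$states) != 0) / 2
  se <- sqrt(pi2 * (1 - pi2) / n_cycles)
  expect_lt(abs(occ - pi2), 3 * se)
})

test_that("render_trace reproduces means, noise level and intensities", {
  states <- list(sim_state("A", 0.2, 0, 1), sim_state("B", 0.448, 0, 1))
  p <- new_path <- structure(list(states = c(1L, 2L, 1L, 2L), labels = c("A", "B"),
                                  frame_time = 0.02), class = "state_path")
  tr <- render_trace(p, states, 1)
  expect_equal(tr$e_star, c(0.2, 0.448, 0.2, 0.448))

  # intensity rendering rule (I_tot = 100)
  tr2 <- render_trace(p, states, 1, emit_intensities = TRUE, i_total = 100)
  expect_equal(tr2$i_da[2], 44.8)
  expect_equal(tr2$i_dd[2], 55.2)
  # round-trip identity through compute_estar
  expect_equal(compute_estar(tr2$i_dd, tr2$i_da), c(0.2, 0.448, 0.2, 0.448))

  # sample SD of the noise matches the configured value within 3 SE
  st <- list(sim_state("S", 0.318, 0.06, 1))
  pp <- structure(list(states = rep(1L, 10000), labels = "S", frame_time = 0.02),
                  class = "state_path")
  e <- render_trace(pp, st, 11)$e_star
  se_sd <- 0.06 / sqrt(2 * 10000)
  expect_lt(abs(sd(e) - 0.06), 3 * se_sd)
})

test_that("make_dataset is deterministic and honours its config", {
  cfg <- sim_config(sim_preset("two-state"), mechanism = c("RP_C", "RP_O"),
                    n_trajectories = 5L, seed = 99L)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1[[3]]$trajectory$e_star, d2[[3]]$trajectory$e_star)
  expect_identical(d1[[3]]$path$states, d2[[3]]$path$states)

  # two-state datasets contain no middle-state frames
  labs <- unlist(lapply(d1, function(it) it$path$labels[it$path$states]))
  expect_false(any(labs == "RP_i"))

  # lengths drawn from the configured range
  lens <- vapply(d1, function(it) length(it$trajectory$e_star), 0L)
  expect_true(all(lens >= 100 & lens <= 350))

  cfg0 <- sim_config(sim_preset("two-state"), mechanism = c("RP_C", "RP_O"),
                     n_trajectories = 0L)
  expect_length(make_dataset(cfg0), 0)
})
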