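#' Calibration state presets
#'
#' `"paper-conservative"` uses the validation-simulation settings: state
#' means 0.196/0.318/0.448 with noise SDs 0.05/0.06/0.05 (15-50% above the
#' experimental noise) and a short closed-complex mean lifetime of 0.16 s,
#' giving a deliberately conservative detection-efficiency estimate.
#' `"experimental-noise"` uses the lower noise SDs measured on experimental
#' data (0.036/0.047/0.040).
#'
#' @param preset Preset name.
#' @return List of [sim_state()] objects (RP_C, RP_i, RP_O).
#' @export
calib_states <- function(preset = c("paper-conservative", "experimental-noise")) {
  preset <- match.arg(preset)
  if (preset == "paper-conservative") sim_preset("three-state") else sim_preset("experimental-noise")
}

#' Simulate bubble-opening trajectories with controlled intermediate dwells
#'
#' Builds RP_C -> (RP_i) -> RP_O trajectories for detection-efficiency
#' calibration. The closed-complex dwell is geometric (mean lifetime
#' `rp_c_tau`, default the conservative 0.16 s); the intermediate dwell is
#' taken from a controlled grid of frame lengths (recycled across
#' trajectories so that dwell-length bins are balanced), drawn
#' exponentially (`rpi_frames = "exponential"`), or absent
#' (`rpi_frames = NULL`, the two-state dataset used for false-positive-rate
#' estimation); the open state absorbs to the trajectory end. Trajectory
#' lengths are drawn uniformly from `length_range` frames; the closed dwell
#' is capped so that at least 10 open-state frames remain.
#'
#' @param n Number of trajectories.
#' @param rpi_frames Integer vector of intermediate dwell lengths in frames,
#'   `"exponential"`, or `NULL` for no intermediate state.
#' @param preset Noise preset, see [calib_states()].
#' @param length_range Trajectory length range in frames (default 100-350,
#'   i.e. 2-7 s).
#' @param frame_time Frame time in seconds.
#' @param rp_c_tau Closed-complex mean lifetime in seconds.
#' @param seed Master seed.
#' @return A `fret_dataset`; each element carries `rpi_frames` (true
#'   intermediate dwell length, 0 if absent) and `rpi_start` (0-based).
#' @export
simulate_opening_dataset <- function(n, rpi_frames = 1:10,
                                     preset = "paper-conservative",
                                     length_range = c(100L, 350L),
                                     frame_time = 0.02, rp_c_tau = 0.16,
                                     seed = 1L) {
  states <- calib_states(preset)
  labels <- vapply(states, `[[`, "", "label")
  has_rpi <- !is.null(rpi_frames)
  if (!has_rpi) states <- states[labels != "RP_i"]
  labels <- vapply(states, `[[`, "", "label")
  i_c <- match("RP_C", labels); i_o <- match("RP_O", labels)
  i_i <- match("RP_i", labels)
  rpi_tau <- if (has_rpi) states[[i_i]]$mean_lifetime else NA_real_
  grid <- if (has_rpi && is.numeric(rpi_frames)) as.integer(rpi_frames) else NULL

  out <- vector("list", n)
  for (t in seq_len(n)) {
    pieces <- with_seed(derive_seed(seed, 2L * t), {
      L <- as.integer(round(runif(1, length_range[1], length_range[2])))
      g <- if (!has_rpi) 0L else if (!is.null(grid)) {
        grid[(t - 1L) %% length(grid) + 1L]
      } else {
        draw_dwell_frames(rpi_tau, frame_time)
      }
      cc <- draw_dwell_frames(rp_c_tau, frame_time)
      cc <- max(1L, min(cc, L - g - 10L))
      list(L = L, g = g, cc = cc)
    })
    st <- c(rep.int(i_c, pieces$cc),
            if (pieces$g > 0L) rep.int(i_i, pieces$g),
            rep.int(i_o, pieces$L - pieces$cc - pieces$g))
    path <- new_state_path(st, labels, frame_time)
    traj <- render_trace(path, states, derive_seed(seed, 2L * t + 1L),
                         id = sprintf("calib%04d", t))
    out[[t]] <- list(trajectory = traj, path = path,
                     rpi_frames = pieces$g, rpi_start = pieces$cc)
  }
  structure(out, class = "fret_dataset",
            config = list(preset = preset, n = n, seed = seed,
                          rp_c_tau = rp_c_tau, frame_time = frame_time,
                          rpi_frames = rpi_frames))
}

#' Simulate dynamic open-complex trajectories
#'
#' Reversible RP_ISO <-> RP_O bubble dynamics at the stated simulation
#' parameters (E* 0.279/0.462, noise SD 0.06, mean lifetimes
#' 0.085 s / 0.56 s), used to calibrate the static/dynamic classifier.
#'
#' @param n Number of trajectories.
#' @param length_range Length range in frames (default 100-350).
#' @param frame_time Frame time in seconds.
#' @param seed Master seed.
#' @return A `fret_dataset`.
#' @export
simulate_dynamic_dataset <- function(n, length_range = c(100L, 350L),
                                     frame_time = 0.02, seed = 1L) {
  cfg <- sim_config(sim_preset("dynamic-rpo"), mechanism = c("RP_ISO", "RP_O"),
                    type = "reversible", frame_time = frame_time,
                    length_frames = length_range, n_trajectories = n, seed = seed)
  make_dataset(cfg)
}

#' Run the bubble-opening analysis on one trajectory
#'
#' Fits 2- and 3-state HMMs (the closed -> open and
#' closed -> intermediate -> open candidate mechanisms), decodes and
#' Allan-filters both paths at the bubble-opening multiplier (2), and
#' applies the mechanism-selection rule. The 3-state fit gets an extra
#' restart seeded from the 2-state fit's means with their midpoint
#' inserted, so a short-lived intermediate between the two main levels is
#' found when present.
#'
#' @param traj A [trajectory()].
#' @param n_restarts EM restarts per fit.
#' @param seed Seed for the fits.
#' @param multiplier Allan acceptance multiplier (default 2).
#' @param allan_m Averaging time (frames) of the filter's Allan estimate
#'   (default 2; see [filter_transitions()]).
#' @return List: `selection` (`"two_state"`/`"three_state"`), `fit2`,
#'   `fit3`, `path2`, `path3`.
#' @export
analyze_opening <- function(traj, n_restarts = 3L, seed = 1L, multiplier = 2,
                            allan_m = 2L) {
  x <- traj$e_star
  fit2 <- fit_hmm(x, 2L, n_restarts, derive_seed(seed, 101L),
                  topology = "chain", var_mode = "fixed")
  # two informed inits: (i) intermediate midway between the 2-state levels;
  # (ii) closed level from the first frames (the trace starts closed), with
  # the intermediate at the 2-state fit's lower level -- targets traces whose
  # closed dwell is too short to register in the 2-state fit
  xf <- x[is.finite(x)]
  fit3 <- fit_hmm(x, 3L, n_restarts, derive_seed(seed, 102L),
                  topology = "chain", var_mode = "fixed",
                  init_means = list(
                    c(fit2$means[1], mean(fit2$means), fit2$means[2]),
                    c(mean(head(xf, 3L)), fit2$means[1], fit2$means[2])))
  ad <- allan_deviation(x, m = allan_m, robust = TRUE)
  f2 <- filter_transitions(viterbi(fit2, x), x, multiplier, allan = ad)
  f3 <- filter_transitions(viterbi(fit3, x), x, multiplier, allan = ad)
  list(selection = select_mechanism(fit2, fit3, f2, f3),
       fit2 = fit2, fit3 = fit3, path2 = f2, path3 = f3)
}

#' Run the post-formation dynamics analysis on one trajectory
#'
#' Fits a 2-state HMM, Allan-filters at the post-formation multiplier (3)
#' and classifies the complex static or dynamic. Before classification a
#' 1-state fit is compared against the 2-state fit; unless both the AIC
#' and the BIC favour two states, the trace is treated as single-state
#' (hence static). This state-pruning gate plays the role of the
#' automatic relevance determination of variational smFRET fitters, which
#' collapse surplus states on featureless traces, and is what keeps the
#' false-dynamic rate on simulated static complexes at zero.
#'
#' @inheritParams analyze_opening
#' @param multiplier Allan acceptance multiplier (default 3).
#' @return List: `class` (`"static"`/`"dynamic"`), `fit`, `path` (the
#'   filtered 2-state path; `NULL` when the 1-state model was kept),
#'   `n_states_kept`.
#' @export
analyze_dynamics <- function(traj, n_restarts = 3L, seed = 1L, multiplier = 3,
                             allan_m = 2L) {
  x <- traj$e_star
  fit1 <- fit_hmm(x, 1L, 1L, derive_seed(seed, 104L))
  fit <- fit_hmm(x, 2L, n_restarts, derive_seed(seed, 103L))
  two_ok <- fit$log_likelihood > fit1$log_likelihood &&
    fit$aic < fit1$aic && fit$bic < fit1$bic
  if (!two_ok) {
    return(list(class = "static", fit = fit1, path = NULL, n_states_kept = 1L))
  }
  ad <- allan_deviation(x, m = allan_m, robust = TRUE)
  f <- filter_transitions(viterbi(fit, x), x, multiplier, allan = ad)
  list(class = classify_dynamics(f), fit = fit, path = f, n_states_kept = 2L)
}

default_bins <- function() {
  data.frame(bin = c("1", "2-4", ">=5"), min_frames = c(1, 2, 5),
             max_frames = c(1, 4, Inf))
}

#' Estimate intermediate-state detection efficiency by true dwell length
#'
#' Runs the full bubble-opening pipeline on a ground-truth dataset and, per
#' dwell-length bin, reports the fraction of true intermediate dwells that
#' were detected. A true dwell counts as detected when the trajectory's
#' selected mechanism is the three-state one and an accepted (interior)
#' middle-state dwell overlaps the true dwell by at least 50% of the true
#' dwell's length. Exact binomial CIs are attached per bin; bins with no
#' true dwells have undefined (NA) efficiency.
#'
#' @param dataset Output of [simulate_opening_dataset()] (with
#'   intermediate dwells spanning the bin range).
#' @param bins data.frame with `bin`, `min_frames`, `max_frames` (default:
#'   1, 2-4, >= 5 frames).
#' @param n_restarts,seed,allan_m Passed to [analyze_opening()].
#' @param min_overlap Required overlap fraction (default 0.5).
#' @return data.frame of class `efficiency_curve`: per bin `n_true`,
#'   `n_detected`, `efficiency`, `ci_lo`, `ci_hi`.
#' @export
estimate_efficiency <- function(dataset, bins = default_bins(), n_restarts = 3L,
                                seed = 1L, allan_m = 2L,
                                min_overlap = 0.5) {
  n_true <- n_det <- integer(nrow(bins))
  for (t in seq_along(dataset)) {
    item <- dataset[[t]]
    g <- item$rpi_frames
    if (is.null(g) || g < 1L) next
    b <- which(bins$min_frames <= g & g <= bins$max_frames)[1]
    if (is.na(b)) next
    n_true[b] <- n_true[b] + 1L
    res <- analyze_opening(item$trajectory, n_restarts = n_restarts,
                           seed = derive_seed(seed, t), allan_m = allan_m)
    if (res$selection != "three_state") next
    dw <- extract_dwells(res$path3, drop_censored = TRUE,
                         frame_time = item$trajectory$frame_time)
    dw <- dw[dw$state == 2L, , drop = FALSE]
    if (!nrow(dw)) next
    a0 <- item$rpi_start; a1 <- a0 + g    # true dwell [a0, a1)
    ov <- pmin(a1, dw$start_frame + dw$length_frames) - pmax(a0, dw$start_frame)
    if (max(ov) >= min_overlap * g) n_det[b] <- n_det[b] + 1L
  }
  eff <- ifelse(n_true > 0, n_det / n_true, NA_real_)
  ci <- t(vapply(seq_len(nrow(bins)), function(i) {
    if (n_true[i] == 0) return(c(NA_real_, NA_real_))
    ci <- exact_binomial_ci(n_det[i], n_true[i])
    c(ci$lo, ci$hi)
  }, numeric(2)))
  out <- cbind(bins, n_true = n_true, n_detected = n_det, efficiency = eff,
               ci_lo = ci[, 1], ci_hi = ci[, 2])
  class(out) <- c("efficiency_curve", "data.frame")
  out
}

#' False-positive rate of intermediate-state calls
#'
#' Fraction of trajectories simulated *without* the intermediate state
#' whose selected mechanism is nonetheless the three-state one.
#'
#' @param dataset Output of `simulate_opening_dataset(n, rpi_frames = NULL)`.
#' @param n_restarts,seed,allan_m Passed to [analyze_opening()].
#' @return List: `rate`, `count`, `n`, `ci` (exact binomial).
#' @export
false_positive_rate <- function(dataset, n_restarts = 3L, seed = 1L,
                                allan_m = 2L) {
  hits <- 0L
  for (t in seq_along(dataset)) {
    g <- dataset[[t]]$rpi_frames
    if (!is.null(g) && g > 0L) stop_input("dataset contains true middle-state frames")
    res <- analyze_opening(dataset[[t]]$trajectory, n_restarts = n_restarts,
                           seed = derive_seed(seed, t), allan_m = allan_m)
    if (res$selection == "three_state") hits <- hits + 1L
  }
  list(rate = hits / length(dataset), count = hits, n = length(dataset),
       ci = exact_binomial_ci(hits, length(dataset)))
}

#' Correct a detected-dwell histogram for missed events
#'
#' Divides each dwell-length bin count by its detection efficiency, turning
#' the histogram of *detected* dwells into an estimate of the histogram of
#' *true* dwells, which can then be fed to [fit_monoexp_hist()].
#'
#' @param hist data.frame with `length_frames` and `count` (one row per
#'   dwell length in frames).
#' @param curve An [estimate_efficiency()] result covering the histogram's
#'   dwell lengths.
#' @return The input data.frame with `efficiency` and `corrected` columns;
#'   bins with undefined efficiency propagate `NA`.
#' @export
correct_dwell_hist <- function(hist, curve) {
  stopifnot(is.data.frame(hist), all(c("length_frames", "count") %in% names(hist)))
  eff <- vapply(hist$length_frames, function(k) {
    b <- which(curve$min_frames <= k & k <= curve$max_frames)[1]
    if (is.na(b)) NA_real_ else curve$efficiency[b]
  }, 0)
  bad <- which(!is.na(eff) & eff == 0 & hist$count > 0)
  if (length(bad)) {
    stop_input("efficiency is 0 in populated bin (length ", hist$length_frames[bad[1]],
               " frames): cannot correct")
  }
  hist$efficiency <- eff
  hist$corrected <- hist$count / eff
  hist
}

#' Expected fraction of trajectories in which the intermediate is detected
#'
#' Combines the dwell-length distribution implied by an exponential
#' intermediate lifetime (geometric in frames at the camera frame time)
#' with a detection-efficiency curve:
#' `sum_bins P(dwell length in bin) * efficiency(bin)`. This is the
#' fraction of trajectories in which the intermediate would be identified
#' if every trajectory passed through it.
#'
#' @param tau Intermediate mean lifetime in seconds (> 0).
#' @param curve An `efficiency_curve` with efficiency defined on all bins.
#' @param frame_time Frame time in seconds.
#' @return Expected detected fraction in `[0, 1]`.
#' @export
expected_detection_fraction <- function(tau, curve, frame_time = 0.02) {
  if (tau <= 0) stop_input("tau must be > 0")
  if (anyNA(curve$efficiency)) stop_input("efficiency undefined on some bins")
  p <- exit_probability(tau, frame_time)
  mass <- vapply(seq_len(nrow(curve)), function(i) {
    a <- curve$min_frames[i]; b <- curve$max_frames[i]
    upper <- if (is.infinite(b)) 1 else pgeom(b - 1, p)
    lower <- if (a <= 1) 0 else pgeom(a - 2, p)
    upper - lower
  }, 0)
  sum(mass * curve$efficiency)
}

#' Fraction of simulated dynamic trajectories classified dynamic
#'
#' Runs the post-formation dynamics pipeline over a dataset and reports the
#' detected-dynamic fraction with its exact binomial CI.
#'
#' @param dataset A `fret_dataset` (e.g. [simulate_dynamic_dataset()]).
#' @param n_restarts,seed,allan_m,multiplier Passed to
#'   [analyze_dynamics()].
#' @return List: `rate`, `count`, `n`, `ci`, `classes` (per-trajectory).
#' @export
dynamic_detection_rate <- function(dataset, n_restarts = 3L, seed = 1L,
                                   multiplier = 3, allan_m = 2L) {
  cls <- vapply(seq_along(dataset), function(t) {
    analyze_dynamics(dataset[[t]]$trajectory, n_restarts = n_restarts,
                     seed = derive_seed(seed, t), multiplier = multiplier,
                     allan_m = allan_m)$class
  }, "")
  hits <- sum(cls == "dynamic")
  list(rate = hits / length(dataset), count = hits, n = length(dataset),
       ci = exact_binomial_ci(hits, length(dataset)), classes = cls)
}
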