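#' Classify a trajectory as static or dynamic
#'
#' A complex is dynamic when its filtered path shows more than two accepted
#' E* transitions, static otherwise (filtering at the post-formation
#' multiplier, 3).
#'
#' @param path A `filtered_path`.
#' @return `"static"` or `"dynamic"`.
#' @export
classify_dynamics <- function(path) {
  stopifnot(inherits(path, "filtered_path"))
  if (nrow(path$accepted_transitions) > 2L) "dynamic" else "static"
}

#' Classify the bubble-opening mechanism of a real-time trajectory
#'
#' Given the two- and three-state fits and their Allan-filtered paths
#' (multiplier 2, the bubble-opening setting), decides whether the
#' closed-to-open transition occurred directly or via the intermediate
#' state, or did not occur at all (`"none"`, e.g. complexes that remain in
#' the low-FRET state). The closed-complex waiting time is the time from
#' the trajectory start (the detected binding moment) to the first accepted
#' opening transition; despite being the first dwell it is not censored,
#' because both of its boundaries are observed events.
#'
#' @param traj A [trajectory()] trimmed to start at promoter binding.
#' @param fit2,fit3 [fit_hmm()] results with `k = 2`, `k = 3`.
#' @param path2,path3 Matching [filter_transitions()] outputs (multiplier 2).
#' @return A list of class `trajectory_class`: `mechanism` (`"direct"`,
#'   `"via_RPi"` or `"none"`), `rp_c_waiting_s`, `rp_i_dwells` (data.frame),
#'   `n_accepted_transitions`.
#' @export
classify_mechanism <- function(traj, fit2, fit3, path2, path3) {
  sel <- select_mechanism(fit2, fit3, path2, path3)
  path <- if (sel == "three_state") path3 else path2
  acc <- path$accepted_transitions
  opening <- acc[acc$from == 1L & acc$to > acc$from, , drop = FALSE]
  frame_time <- traj$frame_time
  if (!nrow(opening) || path$states[1] != 1L) {
    return(structure(list(mechanism = "none", rp_c_waiting_s = NA_real_,
                          rp_i_dwells = extract_dwells(path3, TRUE, frame_time)[0, ],
                          n_accepted_transitions = nrow(acc)),
                     class = "trajectory_class"))
  }
  rp_i <- extract_dwells(path3, drop_censored = TRUE, frame_time = frame_time)
  rp_i <- rp_i[rp_i$state == 2L, , drop = FALSE]
  structure(
    list(mechanism = if (sel == "three_state") "via_RPi" else "direct",
         rp_c_waiting_s = opening$frame[1] * frame_time,
         rp_i_dwells = rp_i,
         n_accepted_transitions = nrow(acc)),
    class = "trajectory_class"
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' 95% exact binomial interval from beta-distribution quantiles. The lower
#' bound is 0 exactly when there are no successes, the upper bound 1
#' exactly when all trials succeed.
#'
#' @param successes,trials Non-negative integers, `successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level (default 0.95).
#' @return A list of class `binomial_ci`: `successes`, `trials`, `point`,
#'   `lo`, `hi`, `level`.
#' @examples
#' exact_binomial_ci(107, 147)
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (!is_count(trials) || trials < 1) stop_input("trials must be a positive integer")
  if (!is_count(successes) || successes > trials) {
    stop_input("successes must be an integer in [0, trials]")
  }
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else qbeta(a, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else qbeta(1 - a, successes + 1, trials - successes)
  structure(list(successes = successes, trials = trials,
                 point = successes / trials, lo = lo, hi = hi, level = level),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (exact %.0f%% CI: %.1f-%.1f%%)\n",
              x$successes, x$trials, 100 * x$point, 100 * x$level,
              100 * x$lo, 100 * x$hi))
  invisible(x)
}

#' Compare replicate-level fractions between two groups
#'
#' Two-sample t-test on per-replicate fractions (e.g. the dynamic-complex
#' fraction in independent experiments). Both the pooled-variance and the
#' unequal-variance (Welch) variants are reported; the pooled variant is
#' the default interpretation of a plain "two-sample t-test".
#'
#' @param group_a,group_b Numeric vectors of replicate fractions (>= 2
#'   each).
#' @return A list with elements `pooled` and `welch`, each holding `t`,
#'   `df`, `p_value`, plus the group means.
#' @export
compare_fractions <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_input("need >= 2 replicates per group")
  }
  pick <- function(tt) list(t = unname(tt$statistic), df = unname(tt$parameter),
                            p_value = tt$p.value)
  list(pooled = pick(t.test(group_a, group_b, var.equal = TRUE)),
       welch = pick(t.test(group_a, group_b, var.equal = FALSE)),
       mean_a = mean(group_a), mean_b = mean(group_b))
}
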