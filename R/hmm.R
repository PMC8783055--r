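#' Fit a K-state Gaussian-emission hidden Markov model to an E* trace
#'
#' Maximum-likelihood fit by Baum-Welch expectation-maximisation, the best
#' of `n_restarts` deterministic restarts. States are returned in canonical
#' order (means sorted ascending). Initialisation uses K-quantiles of the
#' data for the means (evenly spread or jittered on restarts), the squared
#' Allan deviation of the trace as the starting emission variance and
#' 0.9 self-transition probability. Emission variances are per-state and
#' floored at `1e-6` to prevent collapse on noiseless traces. Convergence is
#' declared when the relative log-likelihood change falls below `tol`
#' (default `1e-8`) or after `max_iter` (default 500) iterations.
#'
#' Two transition topologies are supported. `"full"` places no structure on
#' the transition matrix (appropriate for reversible dynamics such as
#' bubble sampling). `"chain"` is a left-to-right mechanism model (state 1
#' -> 2 -> ... -> K, no skipping, last state absorbing), matching the
#' closed -> (intermediate) -> open staircase of first bubble opening; the
#' trajectory then starts in state 1 and states keep their mechanistic
#' order instead of being re-sorted.
#'
#' @param e_star Numeric E* series (NA frames are dropped).
#' @param k Number of states, 1 to 3.
#' @param n_restarts Number of EM restarts (default 5).
#' @param seed Integer seed making the restart jitter reproducible.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param topology `"full"` (default) or `"chain"`.
#' @param var_mode `"free"` (default): per-state emission variances
#'   re-estimated each M-step. `"fixed"`: variances pinned to the squared
#'   Allan deviation of the trace, i.e. the frame-to-frame noise; this is
#'   the maximum-likelihood analogue of the informative noise priors used
#'   by variational smFRET fitters, and it stops a surplus state from
#'   "explaining" a rare intermediate by inflating a neighbour's variance.
#' @param init_means Optional list of extra initial mean vectors, each run
#'   as an additional restart (e.g. a 2-state fit's means with their
#'   midpoint inserted, to seed a rare intermediate state).
#' @return An object of class `hmm_fit` with fields `n_states`, `means`,
#'   `variances`, `transition_matrix`, `initial_probs`, `log_likelihood`,
#'   `aic`, `n_free_params`, `converged`, `n_iterations`, `loglik_trace`.
#'   The AIC uses `n_free_params = k^2 + 2k - 1` for the full topology
#'   (transitions `k(k-1)`, initial `k - 1`, means `k`, variances `k`) and
#'   `3k - 1` for the chain (one free transition probability per
#'   non-terminal state, fixed initial state, means `k`, variances `k`).
#' @export
fit_hmm <- function(e_star, k, n_restarts = 5L, seed = 1L, tol = 1e-8,
                    max_iter = 500L, topology = c("full", "chain"),
                    var_mode = c("free", "fixed"), init_means = NULL) {
  topology <- match.arg(topology)
  var_mode <- match.arg(var_mode)
  if (!k %in% 1:3) stop_input("k must be 1, 2 or 3")
  x <- as.numeric(e_star[is.finite(e_star)])
  if (length(x) < 2L * k) stop_input("fewer than 2k defined frames")
  if (k > 1L && diff(range(x)) < 1e-12) {
    stop_input("degenerate fit: all E* values identical with k > 1")
  }
  var_floor <- 1e-6
  base_means <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  # evenly spaced levels over the bulk of the data range: catches rare states
  # that occupy too few frames to show up in the quantiles
  spread_means <- if (k == 1L) {
    base_means
  } else {
    q <- quantile(x, c(0.02, 0.98), names = FALSE)
    seq(q[1], q[2], length.out = k)
  }
  # initial emission variance from the frame-to-frame noise, not the total
  # variance: a multi-state trace has var(x) far above the emission variance
  v0 <- max(allan_deviation(x)^2, var_floor)
  sd0 <- max(sd(x), sqrt(v0))
  extra <- if (is.null(init_means)) list() else {
    if (!is.list(init_means)) init_means <- list(init_means)
    lapply(init_means, function(m) {
      if (length(m) != k) stop_input("init_means entries must have length k")
      as.numeric(m)
    })
  }
  best <- NULL
  # in free-variance mode one extra restart re-runs the quantile init with a
  # small variance: rescues well-separated or noiseless traces whose Allan
  # deviation is dominated by the signal itself
  n_extra_small <- if (var_mode == "free") 1L else 0L
  n_sched <- n_restarts + length(extra) + n_extra_small
  with_seed(seed, {
    for (r in seq_len(n_sched)) {
      small <- n_extra_small == 1L && r == n_sched
      v_r <- if (small) 1e-4 else v0
      m0 <- if (small) {
        base_means
      } else if (r > n_restarts) {
        extra[[r - n_restarts]]
      } else {
        switch(min(r, 3L),
               base_means,
               spread_means,
               sort(spread_means + rnorm(k, 0, sd0 / 4)))
      }
      if (topology == "chain") {
        tr0 <- diag(0.9, k)
        for (j in seq_len(k - 1)) tr0[j, j + 1L] <- 0.1
        tr0[k, k] <- 1
        p0 <- c(1, rep(0, k - 1L))
      } else {
        tr0 <- matrix(if (k > 1L) 0.1 / (k - 1) else 0, k, k)
        diag(tr0) <- if (k > 1L) 0.9 else 1
        p0 <- rep(1 / k, k)
      }
      fit <- hmm_em_cpp(x, m0, rep(v_r, k), tr0, p0,
                        as.integer(max_iter), tol, var_floor,
                        var_mode == "fixed")
      if (is.null(best) || fit$log_likelihood > best$log_likelihood + 1e-9) best <- fit
    }
  })
  # canonical order: sorted by mean for the full topology; the chain keeps
  # its mechanistic state order (structural zeros pin the identity)
  ord <- if (topology == "chain") seq_len(k) else order(best$means)
  n_free <- if (topology == "chain") 3L * k - 1L else k^2 + 2L * k - 1L
  if (var_mode == "fixed") n_free <- n_free - k  # variances are not fitted
  ll <- best$log_likelihood
  structure(
    list(n_states = as.integer(k),
         means = best$means[ord],
         variances = best$variances[ord],
         transition_matrix = best$transition_matrix[ord, ord, drop = FALSE],
         initial_probs = best$initial_probs[ord],
         log_likelihood = ll,
         aic = 2 * n_free - 2 * ll,
         bic = log(length(x)) * n_free - 2 * ll,
         n_obs = length(x),
         n_free_params = n_free,
         converged = isTRUE(best$converged),
         n_iterations = best$n_iterations,
         loglik_trace = best$loglik_trace,
         topology = topology,
         var_mode = var_mode),
    class = "hmm_fit"
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("%d-state Gaussian HMM: logL = %.2f, AIC = %.2f (%s in %d iter)\n",
              x$n_states, x$log_likelihood, x$aic,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  cat("  means:", paste(sprintf("%.4f", x$means), collapse = ", "), "\n")
  cat("  SDs:  ", paste(sprintf("%.4f", sqrt(x$variances)), collapse = ", "), "\n")
  invisible(x)
}

#' Viterbi decoding of the most probable state path
#'
#' Returns the single most probable path under a fitted model; ties are
#' broken toward the lower state index.
#'
#' @param fit An [fit_hmm()] result.
#' @param e_star Numeric E* series (NA frames dropped, as in the fit).
#' @return An object of class `viterbi_path` with fields `states` (1-based
#'   per-frame state indices over the defined frames) and `state_means`
#'   (decoded E* level per state).
#' @export
viterbi <- function(fit, e_star) {
  stopifnot(inherits(fit, "hmm_fit"))
  x <- as.numeric(e_star[is.finite(e_star)])
  st <- hmm_viterbi_cpp(x, fit$means, fit$variances, fit$transition_matrix,
                        fit$initial_probs)
  structure(list(states = st, state_means = fit$means), class = "viterbi_path")
}

#' Two-state versus three-state mechanism selection
#'
#' The three-state (via-intermediate) model is selected for a trajectory
#' only when all of the following hold: (a) its log-likelihood exceeds the
#' two-state log-likelihood (standing in for the variational lower bound
#' of the reference analysis; both are monotone model-fit scores),
#' (b) its AIC is lower, (c) the fitted levels form a mechanistically
#' valid staircase -- ascending E* with the middle level strictly between
#' the two-state fit's closed and open levels, as expected for an
#' intermediate bubble conformation -- and (d) the Allan-filtered
#' three-state path retains at least one accepted (interior, both
#' transitions accepted) dwell in the middle state. Otherwise the simpler
#' two-state mechanism is kept.
#'
#' With `evidence = "bic"` criterion (a) is replaced by the stricter BIC
#' comparison (the asymptotic approximation to the marginal likelihood a
#' variational bound estimates); this variant suppresses one-frame
#' spurious intermediates almost completely, at the cost of missing most
#' true dwells shorter than five frames, and is provided for conservative
#' re-analysis rather than as the default.
#'
#' @param fit2,fit3 [fit_hmm()] results with `k = 2` and `k = 3`.
#' @param path2,path3 The corresponding [filter_transitions()] outputs
#'   (filtered at the bubble-opening multiplier, 2).
#' @param evidence `"loglik"` (default) or `"bic"`; see Details.
#' @return `"two_state"` or `"three_state"`.
#' @export
select_mechanism <- function(fit2, fit3, path2, path3,
                             evidence = c("loglik", "bic")) {
  evidence <- match.arg(evidence)
  stopifnot(inherits(fit2, "hmm_fit"), inherits(fit3, "hmm_fit"))
  if (!(fit3$log_likelihood > fit2$log_likelihood)) return("two_state")
  if (evidence == "bic" && !(fit3$bic < fit2$bic)) return("two_state")
  if (!(fit3$aic < fit2$aic)) return("two_state")
  if (is.unsorted(fit3$means)) return("two_state")
  if (!(fit3$means[2] > fit2$means[1] && fit3$means[2] < fit2$means[2])) {
    return("two_state")
  }
  dw <- extract_dwells(path3, drop_censored = TRUE)
  if (!any(dw$state == 2L)) return("two_state")
  "three_state"
}
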