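# Shared oracles and fixture builders. Everything is generated in code; no
# stored fixtures.

# Brute-force most-probable-path oracle: enumerate all K^T state paths.
# Returns list(path, logp, unique) where unique indicates the maximum is
# attained by a single path (margin > tol).
brute_viterbi <- function(x, means, vars, trans, init, tol = 1e-9) {
  T <- length(x); K <- length(means)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))[, T:1, drop = FALSE]
  logp <- apply(grid, 1, function(s) {
    lp <- log(init[s[1]]) + dnorm(x[1], means[s[1]], sqrt(vars[s[1]]), log = TRUE)
    if (T > 1) {
      for (t in 2:T) {
        lp <- lp + log(trans[s[t - 1], s[t]]) +
          dnorm(x[t], means[s[t]], sqrt(vars[s[t]]), log = TRUE)
      }
    }
    lp
  })
  best <- which.max(logp)
  list(path = as.integer(grid[best, ]), logp = logp[best],
       unique = sum(logp > logp[best] - tol) == 1L)
}

# Minimal hmm_fit-like object for decoding tests.
manual_fit <- function(means, vars, trans, init) {
  structure(list(n_states = length(means), means = means, variances = vars,
                 transition_matrix = trans, initial_probs = init,
                 log_likelihood = NA_real_, converged = TRUE),
            class = "hmm_fit")
}

# Random valid HMM instance for property tests.
random_hmm <- function(K) {
  tr <- matrix(runif(K * K) + 0.1, K, K)
  tr <- tr / rowSums(tr)
  init <- runif(K) + 0.1
  list(means = sort(runif(K)), vars = runif(K, 0.002, 0.02),
       trans = tr, init = init / sum(init))
}

# Manual viterbi_path builder for filter tests.
manual_path <- function(states, levels) {
  structure(list(states = as.integer(states), state_means = levels),
            class = "viterbi_path")
}

# Frame-quantised exponential dwell sample (seconds): geometric in frames.
sim_dwells <- function(n, tau, frame_time = 0.02) {
  p <- 1 - exp(-frame_time / tau)
  (rgeom(n, p) + 1L) * frame_time
}
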