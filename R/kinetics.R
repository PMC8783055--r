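dwell_times_seconds <- function(dwells) {
  if (is.data.frame(dwells)) {
    if (!is.null(dwells$length_s)) return(dwells$length_s)
    stop_input("dwell data.frame needs a length_s column")
  }
  as.numeric(dwells)
}

# Histogram of dwell times on bins aligned to frame multiples. The first bin
# starts at one frame time, not zero: dwells are at least one frame long, so
# a [0, bw) bin would be structurally empty and bias the exponential fit.
dwell_hist <- function(times, bin_width, frame_time = 0.02) {
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  origin <- min(frame_time, min(times))
  idx <- pmax(floor((times - origin) / bin_width + 1e-9), 0)
  tab <- table(factor(idx, levels = 0:max(idx)))
  counts <- as.integer(tab)
  mids <- origin + (as.integer(names(tab)) + 0.5) * bin_width
  list(mids = mids, counts = counts, bin_width = bin_width)
}

default_bin_width <- function(times, frame_time = 0.02) {
  # 1 frame for short-lived states; 5 frames once the mean dwell exceeds 0.5 s,
  # keeping >= 10 populated bins for the exponential fit
  if (mean(times) > 0.5) 5 * frame_time else frame_time
}

#' Fit a mono-exponential decay to a dwell-time histogram
#'
#' Bins dwell times (bins aligned to frame multiples) and fits
#' `y(t) = A * exp(-t / tau)` to the bin counts at bin centres by unweighted
#' least squares; parameter standard errors come from the fit covariance.
#' `tau` is the state lifetime.
#'
#' @param dwells Dwell data.frame from [extract_dwells()], a numeric vector
#'   of dwell times in seconds, or a precomputed histogram as a list with
#'   `mids` and `counts` (e.g. an efficiency-corrected histogram).
#' @param bin_width Bin width in seconds. Default: 1 frame (0.02 s) for
#'   short-lived states, 5 frames when the mean dwell exceeds 0.5 s.
#' @param frame_time Frame time used by the default binning rule.
#' @return An object of class `exp_fit` with `tau`, `amplitude`, `tau_se`,
#'   `amplitude_se`, `n_dwells`, `bin_width`, `model = "mono"` and the
#'   binned data (`mids`, `counts`).
#' @export
fit_monoexp_hist <- function(dwells, bin_width = NULL, frame_time = 0.02) {
  if (is.list(dwells) && !is.data.frame(dwells) && !is.null(dwells$counts)) {
    h <- dwells
    n <- sum(h$counts)
    if (is.null(h$bin_width)) h$bin_width <- diff(h$mids[1:2])
  } else {
    times <- dwell_times_seconds(dwells)
    if (length(times) < 5L) stop_input("need >= 5 dwells")
    if (is.null(bin_width)) bin_width <- default_bin_width(times, frame_time)
    h <- dwell_hist(times, bin_width, frame_time)
    n <- length(times)
  }
  pop <- h$counts > 0
  if (sum(pop) < 2L) stop_input("singular fit: all dwells in a single bin")
  # start values from a log-linear regression on the populated bins
  lf <- lm(log(h$counts[pop]) ~ h$mids[pop])
  tau0 <- -1 / min(coef(lf)[2], -1e-6)
  a0 <- exp(coef(lf)[1])
  df <- data.frame(t = h$mids, y = h$counts)
  fit <- tryCatch(
    suppressWarnings(nls(y ~ A * exp(-t / tau), data = df,
                         start = list(A = a0, tau = tau0),
                         control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) stop_input("mono-exponential fit failed: ", conditionMessage(e))
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(A = NA_real_, tau = NA_real_))
  structure(
    list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
         tau_se = unname(se["tau"]), amplitude_se = unname(se["A"]),
         n_dwells = n, bin_width = h$bin_width, model = "mono",
         mids = h$mids, counts = h$counts),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "mono") {
    cat(sprintf("mono-exponential fit: tau = %.3f +/- %.3f s, A = %.1f +/- %.1f (n = %d)\n",
                x$tau, x$tau_se, x$amplitude, x$amplitude_se, x$n_dwells))
  } else {
    cat(sprintf("bi-exponential fit: tau1 = %.3f +/- %.3f s, tau2 = %.3f +/- %.3f s [%s]\n",
                x$tau, x$tau_se, x$tau2, x$tau2_se, x$verdict))
  }
  invisible(x)
}

#' Fit a bi-exponential decay and judge whether it is warranted
#'
#' Fits `y(t) = A1 exp(-t/tau1) + A2 exp(-t/tau2)` to the binned dwell
#' times. The more complex model is *rejected* when its parameters are
#' poorly defined: when any relative standard error of the two lifetimes
#' exceeds `se_threshold` (default 0.25), when the two lifetimes are within
#' a factor 1.5 of each other, or when the fit fails outright.
#'
#' @inheritParams fit_monoexp_hist
#' @param se_threshold Maximum tolerated relative SE of the lifetimes.
#' @return An `exp_fit` with `model = "bi"`, fields `tau`, `tau2`,
#'   `amplitude`, `amp2` (+ SEs) and a `verdict` of `"accept"` or
#'   `"reject"` with the reasons in `reasons`.
#' @export
fit_biexp_and_judge <- function(dwells, bin_width = NULL, frame_time = 0.02,
                                se_threshold = 0.25) {
  times <- dwell_times_seconds(dwells)
  if (length(times) < 5L) stop_input("need >= 5 dwells")
  if (is.null(bin_width)) bin_width <- default_bin_width(times, frame_time)
  h <- dwell_hist(times, bin_width, frame_time)
  if (sum(h$counts > 0) < 2L) stop_input("singular fit: all dwells in a single bin")
  df <- data.frame(t = h$mids, y = h$counts)
  m <- mean(times)
  starts <- list(
    list(A1 = 0.7 * max(h$counts), tau1 = m / 3, A2 = 0.3 * max(h$counts), tau2 = 2 * m),
    list(A1 = 0.5 * max(h$counts), tau1 = m / 5, A2 = 0.5 * max(h$counts), tau2 = 3 * m),
    list(A1 = 0.9 * max(h$counts), tau1 = m / 2, A2 = 0.1 * max(h$counts), tau2 = 5 * m)
  )
  fit <- NULL
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(nls(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2),
                           data = df, start = s,
                           control = list(maxiter = 500, warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, tau2 = NA_real_, amplitude = NA_real_,
                          amp2 = NA_real_, tau_se = NA_real_, tau2_se = NA_real_,
                          amplitude_se = NA_real_, amp2_se = NA_real_,
                          n_dwells = length(times), bin_width = bin_width,
                          model = "bi", verdict = "reject",
                          reasons = "fit did not converge"),
                     class = "exp_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  if (is.null(names(se)) || anyNA(names(se))) names(se) <- names(cf)
  # canonical order: tau1 < tau2
  if (cf["tau1"] > cf["tau2"]) {
    cf <- cf[c("A2", "tau2", "A1", "tau1")]
    se <- se[c("A2", "tau2", "A1", "tau1")]
    names(cf) <- names(se) <- c("A1", "tau1", "A2", "tau2")
  }
  rel_se <- abs(se[c("tau1", "tau2")] / cf[c("tau1", "tau2")])
  reasons <- character(0)
  if (anyNA(rel_se) || any(rel_se > se_threshold)) {
    reasons <- c(reasons, sprintf("poorly defined lifetimes (relative SE %s)",
                                  paste(sprintf("%.0f%%", 100 * rel_se), collapse = ", ")))
  }
  if (cf["tau2"] / cf["tau1"] < 1.5) {
    reasons <- c(reasons, "lifetimes within a factor 1.5")
  }
  structure(
    list(tau = unname(cf["tau1"]), tau2 = unname(cf["tau2"]),
         amplitude = unname(cf["A1"]), amp2 = unname(cf["A2"]),
         tau_se = unname(se["tau1"]), tau2_se = unname(se["tau2"]),
         amplitude_se = unname(se["A1"]), amp2_se = unname(se["A2"]),
         n_dwells = length(times), bin_width = bin_width, model = "bi",
         verdict = if (length(reasons)) "reject" else "accept",
         reasons = reasons),
    class = "exp_fit"
  )
}

#' Bootstrap confidence interval for the arithmetic mean dwell time
#'
#' Percentile bootstrap (resampling with replacement) of the sample mean,
#' with a 95% interval from the 2.5 and 97.5 percentiles of `n_boot`
#' resample means.
#'
#' @param dwells Dwell data.frame or numeric vector of dwell times (s).
#' @param n_boot Number of bootstrap iterations (default 10000).
#' @param seed Integer seed; intervals are identical across runs for a
#'   fixed seed.
#' @return A list with `mean`, `lo`, `hi`, `n`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(dwells, n_boot = 10000L, seed = 1L) {
  x <- dwell_times_seconds(dwells)
  n <- length(x)
  if (n < 2L) stop_input("need >= 2 dwells")
  means <- with_seed(seed, {
    chunk <- max(1L, floor(1e7 / n))
    out <- numeric(n_boot)
    done <- 0L
    while (done < n_boot) {
      m <- min(chunk, n_boot - done)
      out[done + seq_len(m)] <- colMeans(matrix(sample(x, n * m, replace = TRUE), nrow = n))
      done <- done + m
    }
    out
  })
  q <- quantile(means, c(0.025, 0.975), names = FALSE)
  list(mean = mean(x), lo = q[1], hi = q[2], n = n, n_boot = n_boot)
}

#' Exponential survival probability
#'
#' The probability that an exponential dwell of mean `tau` exceeds `t`:
#' `exp(-t / tau)`. Used, e.g., to bound the chance that a dynamic complex
#' shows no transition within an observation span.
#'
#' @param tau Mean lifetime in seconds (> 0).
#' @param t Time in seconds (>= 0).
#' @return Probability in `(0, 1]`.
#' @examples
#' survival_exceedance(0.5, 4.26) # ~2e-4
#' @export
survival_exceedance <- function(tau, t) {
  if (tau <= 0) stop_input("tau must be > 0")
  if (any(t < 0)) stop_input("t must be >= 0")
  exp(-t / tau)
}

# Censoring-free maximum-likelihood estimate for cross-checks: for dwell
# lengths measured in whole frames the MLE of the geometric/exponential
# lifetime is tau = -frame_time / log(1 - 1/mean_frames).
mle_lifetime <- function(times, frame_time = 0.02) {
  kbar <- mean(times) / frame_time
  -frame_time / log(1 - 1 / kbar)
}
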