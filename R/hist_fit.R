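#' Build an E* histogram
#'
#' Counts over uniform bins of width `bin_width`, spanning the data range
#' extended outward to bin-width multiples.
#'
#' @param values Numeric E* sample (>= 10 defined values).
#' @param bin_width Bin width in E* units (default 0.02, typical for
#'   published smFRET histograms).
#' @return A list of class `estar_hist`: `counts`, `mids`, `breaks`,
#'   `bin_width`, `n`.
#' @export
build_hist <- function(values, bin_width = 0.02) {
  x <- as.numeric(values[is.finite(values)])
  if (!length(x)) stop_input("empty input")
  if (length(x) < 10L) stop_input("need >= 10 values")
  if (bin_width <= 0) stop_input("bin_width must be > 0")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= max(x)) hi <- hi + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, right = FALSE, plot = FALSE)
  structure(list(counts = h$counts, mids = h$mids, breaks = breaks,
                 bin_width = bin_width, n = length(x)),
            class = "estar_hist")
}

gauss_component <- function(x, A, w, Ec) {
  A / (w * sqrt(pi / 2)) * exp(-2 * (x - Ec)^2 / w^2)
}

#' Fit one or two Gaussian components to an E* histogram
#'
#' Least-squares fit of
#' `y = sum_k A_k / (w_k sqrt(pi/2)) exp(-2 (E* - Ec_k)^2 / w_k^2)`
#' to the bin counts at bin centres. `Ec`, `w` and `A` are the centre,
#' width and area of each component; `w = 2 sigma`, and the integral of a
#' component over E* equals its `A` exactly. Components are reported sorted
#' by centre; standard errors come from the fit covariance. Initialisation
#' uses sample moments (one component) or a k-means split of the binned
#' sample (two components), with jittered restarts on failure.
#'
#' @param hist An [build_hist()] result.
#' @param n_components 1 or 2.
#' @param n_restarts Jittered restarts on non-convergence (default 5).
#' @param seed Seed for k-means and restart jitter.
#' @return A list of class `gauss_fit`: `n_components`, `centers`,
#'   `widths`, `areas`, `center_se`, `width_se`, `area_se`, `bin_width`,
#'   `fitted`.
#' @export
fit_gaussians <- function(hist, n_components = 1L, n_restarts = 5L, seed = 1L) {
  stopifnot(inherits(hist, "estar_hist"))
  if (!n_components %in% 1:2) stop_input("n_components must be 1 or 2")
  pop <- sum(hist$counts > 0)
  if (n_components == 1L && pop < 5L) stop_input("need >= 5 populated bins")
  if (n_components == 2L && pop < 8L) stop_input("need >= 8 populated bins")
  xs <- rep(hist$mids, hist$counts)
  bw <- hist$bin_width
  df <- data.frame(x = hist$mids, y = hist$counts)

  fit <- with_seed(seed, {
    starts <- list()
    if (n_components == 1L) {
      starts[[1]] <- list(A1 = length(xs) * bw, w1 = max(2 * sd(xs), bw),
                          Ec1 = mean(xs))
    } else {
      km <- kmeans(xs, centers = sort(quantile(xs, c(0.25, 0.75), names = FALSE)))
      ord <- order(km$centers)
      s <- vapply(ord, function(g) max(sd(xs[km$cluster == g]), bw / 2), 0)
      nk <- km$size[ord]
      starts[[1]] <- list(A1 = nk[1] * bw, w1 = 2 * s[1], Ec1 = sort(km$centers)[1],
                          A2 = nk[2] * bw, w2 = 2 * s[2], Ec2 = sort(km$centers)[2])
    }
    formula <- if (n_components == 1L) {
      y ~ A1 / (w1 * sqrt(pi / 2)) * exp(-2 * (x - Ec1)^2 / w1^2)
    } else {
      y ~ A1 / (w1 * sqrt(pi / 2)) * exp(-2 * (x - Ec1)^2 / w1^2) +
        A2 / (w2 * sqrt(pi / 2)) * exp(-2 * (x - Ec2)^2 / w2^2)
    }
    out <- NULL
    for (r in seq_len(n_restarts)) {
      s0 <- starts[[1]]
      if (r > 1L) {
        s0 <- lapply(s0, function(v) v * exp(rnorm(1, 0, 0.1)))
      }
      out <- tryCatch(
        nls(formula, data = df, start = s0,
            control = list(maxiter = 500, warnOnly = FALSE)),
        error = function(e) NULL)
      if (!is.null(out)) break
    }
    out
  })
  if (is.null(fit)) stop_input("Gaussian fit did not converge after restarts")
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))),
                 error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  k <- n_components
  centers <- cf[paste0("Ec", seq_len(k))]
  widths <- abs(cf[paste0("w", seq_len(k))])
  areas <- cf[paste0("A", seq_len(k))]
  ord <- order(centers)
  structure(
    list(n_components = k,
         centers = unname(centers[ord]), widths = unname(widths[ord]),
         areas = unname(areas[ord]),
         center_se = unname(se[paste0("Ec", seq_len(k))][ord]),
         width_se = unname(se[paste0("w", seq_len(k))][ord]),
         area_se = unname(se[paste0("A", seq_len(k))][ord]),
         bin_width = bw, fitted = stats::fitted(fit), mids = hist$mids),
    class = "gauss_fit"
  )
}

#' @export
print.gauss_fit <- function(x, ...) {
  for (i in seq_len(x$n_components)) {
    cat(sprintf("component %d: Ec* = %.3f +/- %.3f, w = %.3f, A = %.1f\n",
                i, x$centers[i], x$center_se[i], x$widths[i], x$areas[i]))
  }
  invisible(x)
}

#' Pool E* frames by decoded state across trajectories
#'
#' State-conditional pooling for per-state E* histograms: frames are
#' grouped by the state label of a segmented (filtered) path.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param paths Matching list of `filtered_path`/`viterbi_path` objects.
#' @param state State index to pool (1-based, means-sorted).
#' @return Numeric vector of pooled E* values.
#' @export
pool_state_frames <- function(trajectories, paths, state) {
  stopifnot(length(trajectories) == length(paths))
  unlist(lapply(seq_along(paths), function(i) {
    e <- trajectories[[i]]$e_star
    e <- e[is.finite(e)]
    e[paths[[i]]$states == state]
  }))
}
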