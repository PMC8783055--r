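#' Allan deviation of an E* trace
#'
#' The two-sample Allan deviation at averaging time `m` frames: the trace
#' is block-averaged over non-overlapping windows of `m` frames and the
#' deviation is `sqrt( mean( diff(block means)^2 ) / 2 )`. At `m = 1`
#' (the default) this is the consecutive-frame form; for i.i.d. Gaussian
#' noise of SD sigma it estimates `sigma / sqrt(m)`, while being
#' insensitive to slow drifts -- which is exactly the noise scale against
#' which candidate state transitions are judged.
#'
#' @param e_star Numeric E* series (NA frames dropped).
#' @param m Averaging time in frames (default 1).
#' @param robust If `TRUE`, use the median absolute consecutive difference
#'   scaled to the Gaussian (the estimator is then insensitive to the few
#'   large frame differences contributed by genuine state transitions).
#'   Default `FALSE`: the plain mean-square form.
#' @return Non-negative scalar.
#' @examples
#' allan_deviation(rep(0.4, 100)) # 0
#' @export
allan_deviation <- function(e_star, m = 1L, robust = FALSE) {
  x <- as.numeric(e_star[is.finite(e_star)])
  if (m > 1L) {
    nb <- floor(length(x) / m)
    if (nb < 2L) stop_input("allan_deviation needs >= 2 blocks of m frames")
    x <- colMeans(matrix(x[seq_len(nb * m)], nrow = m))
  }
  if (length(x) < 2L) stop_input("allan_deviation needs >= 2 defined frames")
  d <- diff(x)
  if (robust) {
    # median(|d|) = sigma*sqrt(2)*qnorm(3/4) for Gaussian increments
    stats::median(abs(d)) / (sqrt(2) * stats::qnorm(0.75))
  } else {
    sqrt(mean(d^2) / 2)
  }
}

#' Filter HMM transitions by step size against the Allan deviation
#'
#' Implements the acceptance rule for decoded state transitions: a
#' transition is genuine only if the step in the decoded E* level exceeds
#' `multiplier` times the trace's Allan deviation. Rejected transitions are
#' removed by merging the shorter flanking dwell into the neighbour whose
#' decoded level is nearest (ties merge backward in time); merging iterates
#' until every remaining transition passes. The multiplier is 3 for
#' post-formation bubble dynamics and 2 for first bubble-opening analysis.
#'
#' @param path A `viterbi_path` (or an already filtered path, on which the
#'   operation is idempotent).
#' @param e_star The E* series the path was decoded from.
#' @param multiplier Acceptance multiplier (> 0); conventionally 2 or 3.
#' @param allan Optional externally supplied noise scale; defaults to
#'   `allan_deviation(e_star, m = allan_m)`.
#' @param allan_m Averaging time (frames) of the default Allan estimate.
#'   The pipeline wrappers use `allan_m = 2`: a decoded step is a contrast
#'   between dwell-averaged levels, so its uncertainty is set by the Allan
#'   deviation at the shortest accepted dwell averaging time (2 frames),
#'   not by the raw per-frame noise.
#' @param robust Use the median-based Allan estimator (see
#'   [allan_deviation()]); the pipeline wrappers set this so that the many
#'   genuine steps of a strongly dynamic trace do not inflate the noise
#'   estimate and mask themselves.
#' @return An object of class `filtered_path` with fields `states`
#'   (per-frame state indices after merging), `state_means`,
#'   `accepted_transitions` (data.frame: `frame` of the first frame of the
#'   destination dwell, 0-based; `from`; `to`; `delta_e`), `allan_dev`,
#'   `multiplier`.
#' @export
filter_transitions <- function(path, e_star, multiplier, allan = NULL,
                               allan_m = 1L, robust = FALSE) {
  if (!is.null(multiplier) && multiplier <= 0) stop_input("multiplier must be > 0")
  if (is.null(allan)) allan <- allan_deviation(e_star, m = allan_m, robust = robust)
  thr <- multiplier * allan
  levels <- path$state_means
  st <- path$states
  repeat {
    r <- rle(st)
    if (length(r$values) < 2L) break
    lev <- levels[r$values]
    d <- abs(diff(lev))
    bad <- which(d <= thr)
    if (!length(bad)) break
    i <- bad[which.min(d[bad])]       # boundary between dwells i and i+1
    j <- if (r$lengths[i] < r$lengths[i + 1L]) i else i + 1L
    nb <- c(if (j > 1L) j - 1L, if (j < length(r$values)) j + 1L)
    if (length(nb) == 2L) {
      dd <- abs(levels[r$values[nb]] - levels[r$values[j]])
      nb <- if (dd[2] < dd[1]) nb[2] else nb[1]  # tie -> merge backward
    }
    r$values[j] <- r$values[nb]
    st <- inverse.rle(r)
  }
  r <- rle(st)
  acc <- if (length(r$values) > 1L) {
    bnd <- cumsum(r$lengths)[-length(r$lengths)]  # 0-based frame of next dwell
    data.frame(frame = bnd,
               from = r$values[-length(r$values)],
               to = r$values[-1L],
               delta_e = diff(levels[r$values]))
  } else {
    data.frame(frame = integer(0), from = integer(0), to = integer(0),
               delta_e = numeric(0))
  }
  structure(list(states = st, state_means = levels,
                 accepted_transitions = acc, allan_dev = allan,
                 multiplier = multiplier),
            class = "filtered_path")
}

#' Extract dwells from a (filtered) state path
#'
#' Run-length encodes the per-frame states into dwells. The first and last
#' dwell of a trace have undefined length (left/right censored by the
#' observation window); with `drop_censored = TRUE` they are excluded, as
#' required before compiling dwell-time distributions. The closed-complex
#' waiting time in real-time binding trajectories is the one exception
#' (bounded by the detected binding moment and the accepted opening
#' transition); it is computed by [classify_mechanism()], not here.
#'
#' @param path A `filtered_path`, `viterbi_path` or `state_path`.
#' @param drop_censored Drop the first and last dwell.
#' @param frame_time Frame time in seconds used for `length_s` (taken from
#'   the path when available).
#' @return A data.frame with columns `state`, `start_frame` (0-based),
#'   `length_frames`, `length_s`, `left_censored`, `right_censored`.
#' @export
extract_dwells <- function(path, drop_censored = FALSE, frame_time = NULL) {
  if (is.null(frame_time)) {
    frame_time <- if (!is.null(path$frame_time)) path$frame_time else 0.02
  }
  r <- rle(path$states)
  n <- length(r$values)
  dw <- data.frame(
    state = r$values,
    start_frame = c(0L, cumsum(r$lengths)[-n]),
    length_frames = r$lengths,
    length_s = r$lengths * frame_time,
    left_censored = seq_len(n) == 1L,
    right_censored = seq_len(n) == n
  )
  if (drop_censored) dw <- dw[!dw$left_censored & !dw$right_censored, , drop = FALSE]
  rownames(dw) <- NULL
  dw
}
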