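#' FRET trajectory container
#'
#' Holds per-frame intensity channels and/or the apparent FRET efficiency
#' series for one molecule, at a fixed frame time. If intensity channels are
#' given and `e_star` is not, E* is computed with [compute_estar()]. Frames
#' where `I_DD + I_DA <= 0` carry an undefined (`NA`) E* and are excluded
#' from downstream fits.
#'
#' @param frame_time Frame time in seconds (> 0).
#' @param i_dd,i_da Donor-excitation donor/acceptor emission intensities
#'   (arbitrary units); optional if `e_star` is supplied.
#' @param i_aa Optional acceptor-excitation acceptor emission channel.
#' @param e_star Optional per-frame apparent FRET efficiency.
#' @param id Trajectory identifier string.
#' @return An object of class `fret_trajectory`.
#' @export
trajectory <- function(frame_time, i_dd = NULL, i_da = NULL, i_aa = NULL,
                       e_star = NULL, id = "traj") {
  if (!is.numeric(frame_time) || frame_time <= 0) stop_input("frame_time must be > 0")
  lens <- lengths(Filter(Negate(is.null), list(i_dd, i_da, i_aa, e_star)))
  if (!length(lens)) stop_input("need intensities or e_star")
  if (length(unique(lens)) != 1L) stop_input("channel length mismatch")
  if (lens[1] < 2L) stop_input("trajectory must have >= 2 frames")
  if (is.null(e_star)) {
    if (is.null(i_dd) || is.null(i_da)) stop_input("need both i_dd and i_da, or e_star")
    e_star <- compute_estar(i_dd, i_da)
  }
  structure(
    list(id = id, frame_time = frame_time, i_dd = i_dd, i_da = i_da,
         i_aa = i_aa, e_star = e_star),
    class = "fret_trajectory"
  )
}

#' @export
print.fret_trajectory <- function(x, ...) {
  cat("FRET trajectory", x$id, "-", length(x$e_star), "frames @",
      x$frame_time * 1000, "ms;",
      if (is.null(x$i_dd)) "E*-only" else "with intensities", "\n")
  invisible(x)
}

#' Apparent FRET efficiency from donor-excitation channels
#'
#' The uncorrected proximity ratio `E* = I_DA / (I_DA + I_DD)`. Frames with
#' non-positive summed intensity are undefined and returned as `NA`; they are
#' excluded from all downstream fits rather than imputed.
#'
#' @param i_dd Donor-emission intensity series (donor excitation).
#' @param i_da Acceptor-emission intensity series (donor excitation).
#' @return Numeric E* series of the same length.
#' @examples
#' compute_estar(55, 45) # 0.45
#' @export
compute_estar <- function(i_dd, i_da) {
  if (length(i_dd) != length(i_da)) stop_input("i_dd and i_da length mismatch")
  tot <- i_dd + i_da
  e <- ifelse(tot > 0, i_da / tot, NA_real_)
  as.numeric(e)
}

#' Detect the promoter-binding frame from an intensity step
#'
#' The moment of promoter binding appears in real-time trajectories as an
#' abrupt simultaneous increase of the donor and acceptor fluorescence. This
#' detector scans the summed donor-excitation intensity `I_DD + I_DA` and
#' returns the first frame at which the signal rises clearly above the
#' pre-binding baseline (frame value above the baseline mean by
#' `threshold_sd / 2` baseline SDs) and *stays* above it: the mean over the
#' `persistence`-frame window starting there must exceed the baseline mean
#' by `threshold_sd` standard errors of that window mean (baseline SD /
#' sqrt(persistence)). Testing the window mean against its own standard
#' error keeps single-frame noise from vetoing a genuine step, while the
#' onset gate pins the changepoint to the first elevated frame.
#'
#' @param traj A [trajectory()] with intensity channels.
#' @param threshold_sd Threshold in baseline SD units (default 5).
#' @param persistence Required consecutive frames above threshold (default 3).
#' @param min_baseline Minimum number of baseline frames before a candidate
#'   step can be evaluated (default 10).
#' @return 0-based frame index of the step, or `NA_integer_` if no step.
#' @export
detect_binding <- function(traj, threshold_sd = 5, persistence = 3L,
                           min_baseline = 10L) {
  stopifnot(inherits(traj, "fret_trajectory"))
  if (is.null(traj$i_dd) || is.null(traj$i_da)) stop_input("intensity channels required")
  tot <- traj$i_dd + traj$i_da
  n <- length(tot)
  if (n < min_baseline + persistence) stop_input("trajectory shorter than persistence window")
  for (t in seq.int(min_baseline + 1L, n - persistence + 1L)) {
    base <- tot[seq_len(t - 1L)]
    mu <- mean(base); s <- sd(base)
    if (tot[t] > mu + threshold_sd / 2 * s &&
        mean(tot[t:(t + persistence - 1L)]) > mu + threshold_sd * s / sqrt(persistence)) {
      return(t - 1L)  # 0-based
    }
  }
  NA_integer_
}

trajectory_columns <- c("frame", "time_s", "I_DD", "I_DA", "I_AA", "E_star", "true_state")

#' Write trajectories as tabular text files
#'
#' One comma-separated file per trajectory with the header
#' `frame,time_s,I_DD,I_DA,I_AA,E_star,true_state` (0-based frames), plus a
#' `manifest.txt` listing ids, lengths and, for simulated datasets, the
#' generating seed and parameters.
#'
#' @param dataset A `fret_dataset` (pairs of trajectory + truth path) or a
#'   plain list of [trajectory()] objects.
#' @param path Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_trajectories <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  is_ds <- inherits(dataset, "fret_dataset")
  files <- character(0)
  for (i in seq_along(dataset)) {
    item <- dataset[[i]]
    traj <- if (is_ds || (is.list(item) && !is.null(item$trajectory))) item$trajectory else item
    truth <- if (is.list(item) && !is.null(item$path)) item$path else NULL
    n <- length(traj$e_star)
    df <- data.frame(
      frame = seq_len(n) - 1L,
      time_s = (seq_len(n) - 1L) * traj$frame_time,
      I_DD = if (is.null(traj$i_dd)) NA_real_ else traj$i_dd,
      I_DA = if (is.null(traj$i_da)) NA_real_ else traj$i_da,
      I_AA = if (is.null(traj$i_aa)) NA_real_ else traj$i_aa,
      E_star = traj$e_star,
      true_state = if (is.null(truth)) NA_character_ else truth$labels[truth$states]
    )
    f <- file.path(path, paste0(traj$id, ".csv"))
    write.csv(df, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  cfg <- attr(dataset, "config")
  man <- c(
    paste0("n_trajectories: ", length(dataset)),
    paste0("files: ", paste(basename(files), collapse = ",")),
    if (!is.null(cfg)) c(
      paste0("seed: ", cfg$seed),
      paste0("frame_time: ", cfg$frame_time),
      paste0("mechanism: ", paste(cfg$mechanism, collapse = "->")),
      paste0("type: ", cfg$type),
      paste0("states: ", paste(vapply(cfg$states, function(s) {
        sprintf("%s(mean=%g,sd=%g,tau=%g)", s$label, s$mean_estar, s$noise_sd,
                s$mean_lifetime)
      }, ""), collapse = "; "))
    )
  )
  writeLines(man, file.path(path, "manifest.txt"))
  invisible(files)
}

#' Read trajectories from tabular text files
#'
#' Reads back the format written by [write_trajectories()]. Missing optional
#' columns (intensities, `I_AA`, `true_state`) are tolerated; unknown
#' columns are ignored with a warning; a non-numeric cell in a numeric
#' column raises a parse error naming the file and line.
#'
#' @param path Directory containing `*.csv` trajectory files, or a character
#'   vector of file paths.
#' @param frame_time Frame time in seconds used when a file lacks a usable
#'   `time_s` column (default 0.02).
#' @return A list of [trajectory()] objects; ground-truth labels, when
#'   present, are attached as attribute `true_state`.
#' @export
read_trajectories <- function(path, frame_time = 0.02) {
  files <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  } else {
    path
  }
  lapply(files, read_one_trajectory, frame_time = frame_time)
}

read_one_trajectory <- function(file, frame_time = 0.02) {
  df <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = NA)
  unknown <- setdiff(names(df), trajectory_columns)
  if (length(unknown)) {
    warning("ignoring unknown column(s) in ", basename(file), ": ",
            paste(unknown, collapse = ", "), call. = FALSE)
    df <- df[intersect(names(df), trajectory_columns)]
  }
  num_cols <- setdiff(intersect(names(df), trajectory_columns), "true_state")
  for (col in num_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & v != "" & toupper(v) != "NA")
      if (length(bad)) {
        stop_input(sprintf("parse error in %s line %d: non-numeric value '%s' in column %s",
                           basename(file), bad[1] + 1L, v[bad[1]], col))
      }
      df[[col]] <- suppress
    }
  }
  ft <- if (!is.null(df$time_s) && sum(is.finite(df$time_s)) > 1L) {
    stats::median(diff(df$time_s[is.finite(df$time_s)]))
  } else {
    frame_time
  }
  has <- function(col) !is.null(df[[col]]) && any(is.finite(df[[col]]))
  traj <- trajectory(
    frame_time = ft,
    i_dd = if (has("I_DD")) df$I_DD else NULL,
    i_da = if (has("I_DA")) df$I_DA else NULL,
    i_aa = if (has("I_AA")) df$I_AA else NULL,
    e_star = if (!is.null(df$E_star)) df$E_star else NULL,
    id = sub("\\.csv$", "", basename(file))
  )
  if (!is.null(df$true_state) && any(!is.na(df$true_state))) {
    attr(traj, "true_state") <- as.character(df$true_state)
  }
  traj
}
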