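#' Read a plain-text key/value run configuration
#'
#' One `key: value` pair per line; `#` starts a comment. Values that parse
#' as numbers become numeric; comma-separated values become vectors.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_input("malformed config line: ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    parts <- trimws(strsplit(val, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

empty_report <- function() {
  list(
    trajectory_table = data.frame(id = character(0), n_frames = integer(0),
                                  allan_dev = numeric(0), mechanism = character(0),
                                  dynamics = character(0),
                                  n_accepted_transitions = integer(0),
                                  rp_c_waiting_s = numeric(0)),
    population_table = data.frame(metric = character(0), successes = integer(0),
                                  trials = integer(0), fraction = numeric(0),
                                  ci_lo = numeric(0), ci_hi = numeric(0)),
    kinetics_table = data.frame(state = character(0), n = integer(0),
                                tau = numeric(0), tau_se = numeric(0),
                                amplitude = numeric(0), amplitude_se = numeric(0))
  )
}

#' Run the end-to-end trajectory analysis pipeline
#'
#' For every input trajectory: bubble-opening mechanism classification
#' (2- vs 3-state HMM, Allan filter at multiplier 2) and/or post-formation
#' static/dynamic classification (2-state HMM, multiplier 3); then
#' population fractions with exact binomial CIs and dwell-time kinetics.
#' All randomness derives from `config$seed`, so a rerun with the same
#' config yields identical tables.
#'
#' @param config A named list (or path to a key/value file readable by
#'   [read_run_config()]) with entries: `input` (directory of trajectory
#'   CSV files) or `trajectories` (list of [trajectory()] objects);
#'   `analysis` (`"opening"`, `"dynamics"` or `"both"`, default `"both"`);
#'   `seed` (default 1); `n_restarts` (default 3); `out_dir` (optional:
#'   write report tables as CSV plus a run manifest).
#' @return A list of class `fret_report` with `trajectory_table`,
#'   `population_table`, `kinetics_table` and the effective `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- list(analysis = "both", seed = 1L, n_restarts = 3L,
              frame_time = 0.02)
  cfg[names(config)] <- config
  trajs <- if (!is.null(cfg$trajectories)) {
    cfg$trajectories
  } else if (!is.null(cfg$input)) {
    read_trajectories(cfg$input, frame_time = cfg$frame_time)
  } else {
    list()
  }
  report <- empty_report()
  if (!length(trajs)) {
    warning("empty input: producing empty report", call. = FALSE)
  } else {
    do_open <- cfg$analysis %in% c("opening", "both")
    do_dyn <- cfg$analysis %in% c("dynamics", "both")
    rows <- vector("list", length(trajs))
    rpc_waits <- numeric(0)
    rpo_dwells <- list()
    for (i in seq_along(trajs)) {
      tr <- trajs[[i]]
      mech <- NA_character_; dynamics <- NA_character_
      n_acc <- NA_integer_; wait <- NA_real_; ad <- allan_deviation(tr$e_star)
      if (do_open) {
        res <- analyze_opening(tr, n_restarts = cfg$n_restarts,
                               seed = derive_seed(cfg$seed, 10000L + i))
        cls <- classify_mechanism(tr, res$fit2, res$fit3, res$path2, res$path3)
        mech <- cls$mechanism
        wait <- cls$rp_c_waiting_s
        if (!is.na(wait)) rpc_waits <- c(rpc_waits, wait)
      }
      if (do_dyn) {
        res_d <- analyze_dynamics(tr, n_restarts = cfg$n_restarts,
                                  seed = derive_seed(cfg$seed, 20000L + i))
        dynamics <- res_d$class
        n_acc <- if (is.null(res_d$path)) 0L else nrow(res_d$path$accepted_transitions)
        if (dynamics == "dynamic") {
          dw <- extract_dwells(res_d$path, drop_censored = TRUE,
                               frame_time = tr$frame_time)
          rpo_dwells[[length(rpo_dwells) + 1L]] <- dw
        }
      }
      rows[[i]] <- data.frame(id = tr$id, n_frames = length(tr$e_star),
                              allan_dev = ad, mechanism = mech,
                              dynamics = dynamics, n_accepted_transitions = n_acc,
                              rp_c_waiting_s = wait)
    }
    report$trajectory_table <- do.call(rbind, rows)
    pop <- list()
    add_pop <- function(metric, s, n) {
      if (n > 0) {
        ci <- exact_binomial_ci(s, n)
        pop[[length(pop) + 1L]] <<- data.frame(metric = metric, successes = s,
                                               trials = n, fraction = ci$point,
                                               ci_lo = ci$lo, ci_hi = ci$hi)
      }
    }
    tt <- report$trajectory_table
    if (do_dyn) {
      n_cls <- sum(!is.na(tt$dynamics))
      add_pop("dynamic_fraction", sum(tt$dynamics == "dynamic", na.rm = TRUE), n_cls)
      add_pop("static_fraction", sum(tt$dynamics == "static", na.rm = TRUE), n_cls)
    }
    if (do_open) {
      opened <- sum(tt$mechanism %in% c("direct", "via_RPi"))
      add_pop("via_RPi_fraction", sum(tt$mechanism == "via_RPi", na.rm = TRUE),
              opened)
    }
    if (length(pop)) report$population_table <- do.call(rbind, pop)
    kin <- list()
    if (do_open && length(rpc_waits) >= 5L) {
      f <- tryCatch(fit_monoexp_hist(rpc_waits, frame_time = cfg$frame_time),
                    error = function(e) NULL)
      if (!is.null(f)) {
        kin[[length(kin) + 1L]] <- data.frame(state = "RP_C_waiting",
                                              n = f$n_dwells, tau = f$tau,
                                              tau_se = f$tau_se, amplitude = f$amplitude,
                                              amplitude_se = f$amplitude_se)
      }
    }
    if (do_dyn && length(rpo_dwells)) {
      all_dw <- do.call(rbind, rpo_dwells)
      for (st in sort(unique(all_dw$state))) {
        sub <- all_dw[all_dw$state == st, , drop = FALSE]
        if (nrow(sub) < 5L) next
        f <- tryCatch(fit_monoexp_hist(sub, frame_time = cfg$frame_time),
                      error = function(e) NULL)
        if (!is.null(f)) {
          kin[[length(kin) + 1L]] <- data.frame(state = paste0("state", st),
                                                n = f$n_dwells, tau = f$tau,
                                                tau_se = f$tau_se, amplitude = f$amplitude,
                                                amplitude_se = f$amplitude_se)
        }
      }
    }
    if (length(kin)) report$kinetics_table <- do.call(rbind, kin)
  }
  report$config <- cfg
  class(report) <- "fret_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$trajectory_table, file.path(out_dir, "trajectories.csv"),
            row.names = FALSE)
  write.csv(report$population_table, file.path(out_dir, "population.csv"),
            row.names = FALSE)
  write.csv(report$kinetics_table, file.path(out_dir, "kinetics.csv"),
            row.names = FALSE)
  cfg <- report$config
  keep <- vapply(cfg, function(v) is.character(v) || is.numeric(v) || is.logical(v), TRUE)
  writeLines(c(paste0("generated_by: fretpath ", as.character(utils::packageVersion("fretpath"))),
               vapply(names(cfg)[keep], function(k) {
                 paste0(k, ": ", paste(cfg[[k]], collapse = ","))
               }, "")),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

#' @export
print.fret_report <- function(x, ...) {
  cat("fretpath run report:", nrow(x$trajectory_table), "trajectories\n")
  if (nrow(x$population_table)) {
    print(x$population_table, row.names = FALSE)
  }
  if (nrow(x$kinetics_table)) {
    print(x$kinetics_table, row.names = FALSE)
  }
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a simulated dataset),
#' `analyze` (run [run_pipeline()] on a directory of trajectory files),
#' `calibrate` (detection-efficiency + false-positive calibration),
#' `convert` (intensity files to E*-only files), `fit` (per-trajectory HMM
#' fits; flags `--k`, `--restarts`, `--seed`, `--tol`), `hist` (pooled E*
#' histogram Gaussian fit; flags `--bins`, `--components`), `report`
#' (re-run analyze and print the report). Flags are `--key value` pairs.
#'
#' @param args Character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the result object of the subcommand.
#' @export
fretpath_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: fretpath <simulate|analyze|calibrate|convert|fit|hist|report> [--key value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) >= 2L && startsWith(rest[1], "--")) {
    key <- sub("^--", "", rest[1])
    val <- rest[2]
    num <- suppressWarnings(as.numeric(val))
    opts[[key]] <- if (!is.na(num)) num else val
    rest <- rest[-(1:2)]
  }
  get_opt <- function(name, default) if (!is.null(opts[[name]])) opts[[name]] else default
  res <- switch(cmd,
    simulate = {
      preset <- get_opt("preset", "three-state")
      n <- as.integer(get_opt("n", 10))
      seed <- as.integer(get_opt("seed", 1))
      out <- get_opt("out", "sim_out")
      states <- sim_preset(preset)
      type <- if (preset == "dynamic-rpo") "reversible" else "chain"
      ds <- make_dataset(sim_config(states, type = type, n_trajectories = n,
                                    seed = seed))
      write_trajectories(ds, out)
      cat("wrote", n, "trajectories to", out, "\n")
      ds
    },
    analyze = ,
    report = {
      rep <- run_pipeline(list(input = get_opt("input", "."),
                               analysis = get_opt("analysis", "both"),
                               seed = as.integer(get_opt("seed", 1)),
                               n_restarts = as.integer(get_opt("restarts", 3)),
                               out_dir = opts[["out"]]))
      print(rep)
      rep
    },
    calibrate = {
      preset <- get_opt("preset", "paper-conservative")
      n <- as.integer(get_opt("n", 100))
      seed <- as.integer(get_opt("seed", 1))
      ds <- simulate_opening_dataset(n, preset = preset, seed = seed)
      curve <- estimate_efficiency(ds, seed = derive_seed(seed, 7L))
      print(as.data.frame(curve), row.names = FALSE)
      curve
    },
    fit = {
      trajs <- read_trajectories(get_opt("input", "."))
      k <- as.integer(get_opt("k", 2))
      for (tr in trajs) {
        fit <- fit_hmm(tr$e_star, k,
                       n_restarts = as.integer(get_opt("restarts", 5)),
                       seed = as.integer(get_opt("seed", 1)),
                       tol = as.numeric(get_opt("tol", 1e-8)))
        cat("==", tr$id, "==\n")
        print(fit)
      }
      invisible(NULL)
    },
    hist = {
      trajs <- read_trajectories(get_opt("input", "."))
      pooled <- unlist(lapply(trajs, `[[`, "e_star"))
      h <- build_hist(pooled, bin_width = as.numeric(get_opt("bins", 0.02)))
      gfit <- fit_gaussians(h, n_components = as.integer(get_opt("components", 1)),
                            seed = as.integer(get_opt("seed", 1)))
      print(gfit)
      gfit
    },
    convert = {
      trajs <- read_trajectories(get_opt("input", "."))
      out <- get_opt("out", "converted")
      eonly <- lapply(trajs, function(tr) {
        trajectory(frame_time = tr$frame_time, e_star = tr$e_star, id = tr$id)
      })
      write_trajectories(eonly, out)
      cat("wrote", length(eonly), "E*-only files to", out, "\n")
      invisible(out)
    },
    stop_input("unknown subcommand: ", cmd)
  )
  invisible(res)
}
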