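#' Run the full coordination-kinetics protocol
#'
#' Orchestrates the standard workflow: obtain a free-energy profile (from a
#' trajectory, a profile file, or a synthetic preset), partition it into
#' coordination states, assign trajectory frames (when a trajectory is
#' available), estimate the position-dependent diffusion coefficient, and
#' compute the MFPT matrix for every adjacent state pair by the requested
#' methods, optionally followed by a committor scan. Any stage failure
#' aborts with the stage name and a remedy hint.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{preset}{name of an [ion_preset()] ("ca", "zn", "hg", "cd");
#'       used for profile/diffusion ground truth when files are absent}
#'     \item{series}{path(s) to COLVAR/TSV trajectory file(s)}
#'     \item{profile}{path to a profile TSV}
#'     \item{diffusion}{path to a diffusion TSV}
#'     \item{temperature}{K, default 300}
#'     \item{n_bins}{histogram bins for profile estimation, default 80}
#'     \item{min_prominence}{state merging threshold, kJ/mol, default 1}
#'     \item{ds, lag}{diffusion-estimation bin width (default 0.1) and lag
#'       time (default 0.5 ps)}
#'     \item{methods}{subset of c("fp", "backward", "kramers", "ld"),
#'       default c("fp", "backward", "kramers")}
#'     \item{n_replicas, seed, dt_ld}{Langevin controls (ld method)}
#'     \item{committor}{logical; scan the committor at each barrier}
#'     \item{out}{optional path for the report JSON}
#'   }
#' @return object of class `hydrokin_report`: list with `config`, `profile`,
#'   `partition`, `diffusion`, `mfpt` (data.frame across methods),
#'   `assigned` (transition_stats or NULL), `committor` (list or NULL)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(temperature = 300, n_bins = 80, min_prominence = 1, ds = 0.1,
         lag = 0.5, methods = c("fp", "backward", "kramers"),
         n_replicas = 1000, seed = 1, dt_ld = 0.002, committor = FALSE),
    config)
  stage <- function(name, hint, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (%s)", name,
                   conditionMessage(e), hint), call. = FALSE)
    })
  }
  preset <- NULL
  if (!is.null(cfg$preset)) preset <- ion_preset(cfg$preset,
                                                 temperature = cfg$temperature)
  series <- NULL
  if (!is.null(cfg$series)) {
    series <- stage("input", "check the trajectory file paths and format",
                    lapply(cfg$series, read_colvar))
  }

  profile <- stage("profile", "supply a profile TSV, a trajectory, or a preset", {
    if (!is.null(cfg$profile)) {
      read_profile_tsv(cfg$profile, temperature = cfg$temperature)
    } else if (!is.null(series)) {
      estimate_profile(unlist(lapply(series, `[[`, "values")),
                       n_bins = cfg$n_bins, temperature = cfg$temperature)
    } else if (!is.null(preset)) {
      preset$profile
    } else {
      stop("no profile source given")
    }
  })

  partition <- stage("partition", "lower min_prominence or inspect the profile",
                     partition_states(profile, cfg$min_prominence))

  assigned <- NULL
  if (!is.null(series)) {
    assigned <- stage("assign", "check that the series covers the partition", {
      stats_list <- lapply(series, function(sr)
        transition_stats(assign_states(sr, partition)))
      if (length(stats_list) == 1) stats_list[[1]] else stats_list
    })
  }

  diffusion <- stage("diffusion",
                     "supply a diffusion TSV or a trajectory to estimate D from", {
    if (!is.null(cfg$diffusion)) {
      read_diffusion_tsv(cfg$diffusion)
    } else if (!is.null(series)) {
      grid <- bin_grid(min(profile$s), max(profile$s), ds = cfg$ds)
      estimate_diffusion(series, grid, lag = cfg$lag, profile = profile)
    } else if (!is.null(preset)) {
      preset$diffusion
    } else {
      stop("no diffusion source given")
    }
  })

  mfpt <- stage("mfpt", "check method names and state adjacency", {
    rows <- list()
    K <- nrow(partition)
    for (i in seq_len(K)) for (j in c(i - 1, i + 1)) {
      if (j < 1 || j > K) next
      from <- partition$label[i]
      to <- partition$label[j]
      for (m in cfg$methods) {
        r <- switch(m,
          fp = mfpt_forward(profile, diffusion, partition, from, to),
          backward = mfpt_backward_states(profile, diffusion, partition,
                                          from, to),
          kramers = mfpt_kramers(profile, diffusion, partition, from, to),
          ld = mfpt_ld(profile, diffusion, partition, from, to,
                       n_replicas = cfg$n_replicas, seed = cfg$seed,
                       dt = cfg$dt_ld),
          stop("unknown method '", m, "'"))
        rows[[length(rows) + 1]] <- r
      }
    }
    do.call(rbind, rows)
  })

  committor <- NULL
  if (isTRUE(cfg$committor) && nrow(partition) > 1) {
    committor <- stage("committor", "reduce n_starts/n_replicas or widen horizon", {
      lapply(seq_len(nrow(partition) - 1), function(k) {
        edge <- partition$right[k]
        committor_ensemble(profile, diffusion,
                           s0_band = edge + c(-0.02, 0.02),
                           partition = partition, seed = cfg$seed)
      })
    })
  }

  report <- structure(list(config = cfg, profile = profile,
                           partition = partition, diffusion = diffusion,
                           mfpt = mfpt, assigned = assigned,
                           committor = committor),
                      class = "hydrokin_report")
  if (!is.null(cfg$out)) {
    write_results_json(report_to_list(report), cfg$out,
                       config = cfg[setdiff(names(cfg), "out")])
  }
  report
}

report_to_list <- function(report) {
  list(partition = as.data.frame(unclass(report$partition)),
       mfpt = as.data.frame(unclass(report$mfpt)),
       diffusion = list(s = report$diffusion$s, D = report$diffusion$D,
                        dD = report$diffusion$dD))
}

#' @export
print.hydrokin_report <- function(x, ...) {
  cat("hydrokin pipeline report\n")
  cat("========================\n")
  print(x$partition)
  cat("\nMFPT (ps) by transition and method:\n")
  m <- x$mfpt
  wide <- stats::reshape(
    transform(m[, c("from", "to", "method", "tau")],
              transition = paste(from, "->", to))[, c("transition", "method", "tau")],
    idvar = "transition", timevar = "method", direction = "wide")
  names(wide) <- sub("^tau\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}
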