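# configuration schema: NA means "any scalar of this kind checked at use
# time"; nested lists validate recursively; "free" children are not checked
.config_schema <- function() {
  list(
    temperature = NA, seed = NA, outdir = NA, stages = NA,
    threshold = NA, half_k = NA, pseudocount = NA, wt = NA,
    bins_r = list(min = NA, max = NA, width = NA),
    bins_theta = list(min = NA, max = NA, width = NA),
    wham = list(tolerance = NA, max_iterations = NA,
                grid_min = NA, grid_max = NA, bin_width = NA),
    potential = list(form = NA, barrier = NA, r_a = NA, r_b = NA,
                     delta_rp = NA, kappa = NA),
    umbrella = list(n_windows = NA, n_per_window = NA,
                    k_min = NA, k_max = NA),
    frames = list(preset = NA, n_frames = NA, mean_r = NA, sd_r = NA,
                  mean_theta = NA, sd_theta = NA, mean_r_cs = NA,
                  sd_r_cs = NA, methylation = NA),
    barriers = "free",
    correction_file = NA,
    frames_file = NA, frames_format = NA,
    role_map = list(s_delta = NA, c_methyl = NA, n_zeta = NA,
                    n_substituents = NA),
    windows_metadata_file = NA
  )
}

.collect_bad_keys <- function(config, schema, prefix = "") {
  bad <- character(0L)
  for (key in names(config)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(schema)) {
      bad <- c(bad, path)
    } else if (is.list(schema[[key]]) && is.list(config[[key]])) {
      bad <- c(bad, .collect_bad_keys(config[[key]], schema[[key]], path))
    }
  }
  bad
}

#' Validate a pipeline configuration
#'
#' Checks every key (recursively) against the configuration schema and
#' reports all unknown keys at once, so a typo like `wham.tolerence` is
#' named rather than silently ignored.
#'
#' @param config a named list, or a path to a YAML configuration file.
#' @return The configuration as a list, invisibly; errors on violations.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a named list or a YAML file path", call. = FALSE)
  }
  if (length(config) > 0L &&
      (is.null(names(config)) || any(!nzchar(names(config))))) {
    stop("every configuration entry must be named", call. = FALSE)
  }
  bad <- .collect_bad_keys(config, .config_schema())
  if (length(bad) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  known_stages <- c("all", "simulate", "geom", "pmf", "triplet", "classify")
  if (!is.null(config$stages) && !all(config$stages %in% known_stages)) {
    stop(sprintf("unknown stage(s): %s",
                 paste(setdiff(config$stages, known_stages),
                       collapse = ", ")), call. = FALSE)
  }
  invisible(config)
}

.cfg <- function(config, key, default) {
  val <- config
  for (k in strsplit(key, ".", fixed = TRUE)[[1L]]) {
    val <- val[[k]]
    if (is.null(val)) return(default)
  }
  val
}

#' Run the methyl-transfer free-energy pipeline end to end
#'
#' Executes the requested stages in dependency order from a single
#' configuration: `simulate` (synthetic frames and umbrella windows, written
#' under `outdir/data`), `geom` (geometry records, 2D distribution,
#' Boltzmann-inverted surface and marginals), `pmf` (WHAM profile,
#' optional correction, barrier), `triplet` and `classify` (triplets and
#' product-specificity calls from the `barriers` block). `"all"` (the
#' default) runs every stage whose inputs are available; partial runs —
#' e.g. only the triplet stage from user-supplied barriers — are
#' first-class. All tables, profiles and a manifest (config, seed, file
#' checksums, accumulated warnings) are written to `outdir`; re-running
#' with an identical configuration and seed reproduces every output
#' byte for byte.
#'
#' @param config named list or YAML file path; validated with
#'   [validate_config()].
#' @return An object of class `pipeline_run`: the expanded config, the
#'   in-memory stage outputs, and the manifest.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  outdir <- .cfg(config, "outdir", stop("config needs `outdir`",
                                        call. = FALSE))
  seed <- .cfg(config, "seed", 1L)
  temperature <- .cfg(config, "temperature", .default_temperature)
  stages <- .cfg(config, "stages", "all")
  half_k <- isTRUE(.cfg(config, "half_k", FALSE))
  if ("all" %in% stages) {
    stages <- c("simulate", "geom", "pmf", "triplet", "classify")
  }
  warnings_seen <- character(0L)
  note <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  out <- list()
  tables <- list()
  profiles <- list()

  if ("simulate" %in% stages) {
    data_dir <- file.path(outdir, "data")
    pot <- make_potential(
      form = .cfg(config, "potential.form", "quartic_double_well"),
      barrier = .cfg(config, "potential.barrier", 13.4),
      r_a = .cfg(config, "potential.r_a", -1.4),
      r_b = .cfg(config, "potential.r_b", 1.2),
      delta_rp = .cfg(config, "potential.delta_rp", 0),
      kappa = .cfg(config, "potential.kappa", NULL))
    proto <- umbrella_protocol(
      pot,
      n_windows = .cfg(config, "umbrella.n_windows", 20),
      k_limits = c(.cfg(config, "umbrella.k_min", 50),
                   .cfg(config, "umbrella.k_max", 400)))
    windows <- gen_umbrella_windows(
      pot, proto$centers, proto$force_constants,
      n_per_window = .cfg(config, "umbrella.n_per_window", 5000),
      temperature = temperature, seed = seed, half_k = half_k)
    note(write_window_series(windows, data_dir))

    out$data_dir <- data_dir
    fspec <- if (!is.null(.cfg(config, "frames.preset", NULL))) {
      frame_preset(.cfg(config, "frames.preset", "reactive_wt_like"),
                   n_frames = .cfg(config, "frames.n_frames", 10000),
                   seed = seed)
    } else {
      frame_ensemble_spec(
        n_frames = .cfg(config, "frames.n_frames", 10000),
        mean_r = .cfg(config, "frames.mean_r", 3.0),
        sd_r = .cfg(config, "frames.sd_r", 0.15),
        mean_theta = .cfg(config, "frames.mean_theta", 30),
        sd_theta = .cfg(config, "frames.sd_theta", 12),
        mean_r_cs = .cfg(config, "frames.mean_r_cs", 1.81),
        sd_r_cs = .cfg(config, "frames.sd_r_cs", 0.02),
        methylation = .cfg(config, "frames.methylation", 0),
        seed = seed)
    }
    frames <- gen_frames(fspec, temperature = temperature)
    write_frames_xyz(frames, file.path(data_dir, "frames.xyz"))
    out$potential <- pot
    out$windows <- windows
    out$frames <- frames
  }

  if ("geom" %in% stages) {
    frames <- out$frames
    if (is.null(frames) && !is.null(.cfg(config, "frames_file", NULL))) {
      rmcfg <- .cfg(config, "role_map", NULL)
      if (is.null(rmcfg)) {
        stop("geom stage from `frames_file` needs a `role_map` block",
             call. = FALSE)
      }
      rm <- role_map(rmcfg$s_delta, rmcfg$c_methyl, rmcfg$n_zeta,
                     rmcfg$n_substituents)
      frames <- read_frames(.cfg(config, "frames_file", NULL),
                            format = .cfg(config, "frames_format", "xyz"),
                            role_map = rm, temperature = temperature)
    }
    if (!is.null(frames)) {
      geo <- compute_geometry(frames)
      bins_r <- seq(.cfg(config, "bins_r.min", 2.0),
                    .cfg(config, "bins_r.max", 6.0),
                    by = .cfg(config, "bins_r.width", 0.05))
      bins_t <- seq(.cfg(config, "bins_theta.min", 0),
                    .cfg(config, "bins_theta.max", 180),
                    by = .cfg(config, "bins_theta.width", 5))
      hist2d <- note(build_histogram2d(geo, bins_r, bins_t))
      surface <- boltzmann_invert(hist2d, temperature,
                                  pseudocount = .cfg(config, "pseudocount",
                                                     0))
      out$geometry <- geo
      out$histogram <- hist2d
      out$surface <- surface
      tables$geometry <- as.data.frame(geo)
      tables$marginal_r <- marginal_free_energy(hist2d, "r", temperature)
      tables$marginal_theta <- marginal_free_energy(hist2d, "theta",
                                                    temperature)
      profiles$surface <- surface
    }
  }

  if ("pmf" %in% stages) {
    windows <- out$windows
    meta_file <- .cfg(config, "windows_metadata_file", NULL)
    if (is.null(windows) && !is.null(meta_file)) {
      meta <- utils::read.csv(meta_file)
      windows <- read_window_series(
        file.path(dirname(meta_file), meta$file), meta, half_k = half_k)
    }
    if (!is.null(windows)) {
      grid <- wham_grid(.cfg(config, "wham.grid_min", -2.5),
                        .cfg(config, "wham.grid_max", 2.5),
                        .cfg(config, "wham.bin_width", 0.05))
      profile <- note(wham_solve(
        windows, temperature = temperature, grid = grid,
        tolerance = .cfg(config, "wham.tolerance", 1e-6),
        max_iterations = .cfg(config, "wham.max_iterations", 1e5)))
      corr_file <- .cfg(config, "correction_file", NULL)
      curve <- if (!is.null(corr_file)) read_correction_curve(corr_file)
               else NULL
      corrected <- note(apply_correction(profile, curve))
      barrier <- note(extract_barrier(corrected))
      out$pmf <- profile
      out$pmf_corrected <- corrected
      out$barrier <- barrier
      profiles$pmf <- profile
      profiles$pmf_corrected <- corrected
      tables$barrier <- data.frame(
        barrier = barrier$barrier, R_reactant = barrier$R_reactant,
        R_TS = barrier$R_TS, F_TS = barrier$F_TS,
        converged = profile$converged, iterations = profile$iterations)
    }
  }

  barrier_cfg <- .cfg(config, "barriers", NULL)
  if (!is.null(barrier_cfg) && any(c("triplet", "classify") %in% stages)) {
    sets <- lapply(names(barrier_cfg), function(nm) {
      barrier_set(nm, as.numeric(barrier_cfg[[nm]]))
    })
    names(sets) <- names(barrier_cfg)
    wt_name <- .cfg(config, "wt", names(sets)[1L])
    if (!wt_name %in% names(sets)) {
      stop(sprintf("wild-type enzyme '%s' not found in `barriers`", wt_name),
           call. = FALSE)
    }
    out$barrier_sets <- sets

    if ("triplet" %in% stages) {
      trips <- lapply(sets, function(s) compute_triplet(sets[[wt_name]], s))
      out$triplets <- trips
      tables$triplets <- do.call(rbind, lapply(trips, function(tr) {
        data.frame(enzyme = tr$enzyme,
                   t1 = .fmt1(tr$triplet[1L]), t2 = .fmt1(tr$triplet[2L]),
                   t3 = .fmt1(tr$triplet[3L]),
                   d1 = .fmt1(tr$within_enzyme_deltas[1L]),
                   d2 = .fmt1(tr$within_enzyme_deltas[2L]),
                   d3 = .fmt1(tr$within_enzyme_deltas[3L]))
      }))
    }
    if ("classify" %in% stages) {
      threshold <- .cfg(config, "threshold", 3.0)
      calls <- lapply(sets, classify_specificity, threshold = threshold)
      out$calls <- calls
      tables$specificity <- do.call(rbind, lapply(calls, function(cl) {
        data.frame(enzyme = cl$enzyme, call = cl$call,
                   threshold = cl$threshold,
                   blocking_step = cl$blocking_step,
                   undetermined_beyond = cl$undetermined_beyond)
      }))
      band <- specificity_threshold_band(
        sets, vapply(calls, `[[`, character(1L), "call"))
      out$threshold_band <- band
      tables$threshold_band <- data.frame(
        lower = band$lower, upper = band$upper, empty = band$empty)
    }
  }

  # the manifest must be identical across runs that differ only in outdir
  config_echo <- config
  config_echo$outdir <- NULL
  input_hashes <- NULL
  if (!is.null(out$data_dir)) {
    data_files <- list.files(out$data_dir, full.names = TRUE)
    input_hashes <- stats::setNames(as.character(tools::md5sum(data_files)),
                                    file.path("data", basename(data_files)))
  }
  manifest <- write_results(tables, profiles, outdir, config = config_echo,
                            seed = seed, input_hashes = input_hashes,
                            warnings = warnings_seen)
  structure(list(config = config, seed = seed, outputs = out,
                 tables = tables, manifest = manifest,
                 warnings = warnings_seen),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> seed %s; outputs: %s\n",
              format(x$seed), paste(names(x$outputs), collapse = ", ")))
  if (length(x$warnings) > 0L) {
    cat(sprintf("  %d warning(s) recorded in the manifest\n",
                length(x$warnings)))
  }
  invisible(x)
}
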