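#' Write tabular results, profiles and a run manifest
#'
#' Writes every table as a CSV (one header row, one record per row), every
#' PMF profile or free-energy surface as a CSV grid, and a JSON manifest
#' recording the package version, the run configuration and seed, input
#' hashes, warnings, and an md5 checksum for every file written. File names
#' inside the manifest are relative to `outdir`, so two runs with identical
#' configuration and seed produce byte-identical output trees.
#'
#' @param tables named list of data frames (may be empty).
#' @param profiles named list of [pmf_profile()] and/or
#'   `free_energy_surface` objects (may be empty).
#' @param outdir output directory, created if needed.
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional seed recorded in the manifest.
#' @param input_hashes optional named character vector of input-file md5s.
#' @param warnings character vector of warnings to persist.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_results <- function(tables = list(), profiles = list(), outdir,
                          config = NULL, seed = NULL,
                          input_hashes = NULL, warnings = character(0L)) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      stop(sprintf("cannot create output directory: %s", outdir),
           call. = FALSE)
    }
  }
  if (file.access(outdir, mode = 2L) != 0L) {
    stop(sprintf("output directory is not writable: %s", outdir),
         call. = FALSE)
  }
  files <- character(0L)

  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], path, row.names = FALSE)
    files <- c(files, path)
  }
  for (nm in names(profiles)) {
    obj <- profiles[[nm]]
    path <- file.path(outdir, paste0(nm, ".csv"))
    if (inherits(obj, "pmf_profile")) {
      utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    } else if (inherits(obj, "free_energy_surface")) {
      utils::write.csv(as.data.frame(obj), path, row.names = FALSE)
    } else {
      stop(sprintf("profile '%s' is neither a pmf_profile nor a free_energy_surface",
                   nm), call. = FALSE)
    }
    files <- c(files, path)
  }

  checksums <- if (length(files) > 0L) {
    h <- tools::md5sum(files)
    names(h) <- basename(files)
    as.list(h)
  } else {
    stats::setNames(list(), character(0L))
  }
  manifest <- list(
    package = "methylpmf",
    version = as.character(utils::packageVersion("methylpmf")),
    seed = seed,
    config = config,
    input_hashes = as.list(input_hashes),
    warnings = warnings,
    files = checksums
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(
    R = x$grid,
    free_energy = x$free_energy,
    defined = !is.na(x$free_energy),
    n_samples = if (is.null(x$n_samples)) NA_integer_ else x$n_samples
  )
}

#' @export
as.data.frame.free_energy_surface <- function(x, ...) {
  rc <- (x$r_edges[-1L] + x$r_edges[-length(x$r_edges)]) / 2
  tc <- (x$theta_edges[-1L] + x$theta_edges[-length(x$theta_edges)]) / 2
  data.frame(
    r_center = rep(rc, times = length(tc)),
    theta_center = rep(tc, each = length(rc)),
    count = as.integer(x$counts),
    free_energy = as.numeric(x$free_energy)
  )
}
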