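#' Construct an umbrella-sampling window
#'
#' One biased simulation window along the SN2 reaction coordinate
#' R = r(CM..Sdelta) - r(CM..Nzeta). The harmonic bias is
#' `w(R) = k (R - center)^2` by default (no 1/2 prefactor, the CHARMM
#' umbrella convention); set `half_k = TRUE` for the
#' `w(R) = k/2 (R - center)^2` convention. The convention travels with the
#' window and [wham_solve()] refuses to mix the two.
#'
#' @param center bias centre on R, angstrom.
#' @param force_constant harmonic force constant, kcal mol^-1 A^-2; zero
#'   means an unbiased window.
#' @param samples numeric vector of sampled R values, angstrom.
#' @param half_k logical; whether the 1/2 prefactor is part of the bias.
#' @param bias_offset additive constant on the bias, kcal/mol (physically
#'   irrelevant gauge term, kept to make gauge invariance testable).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples,
                            half_k = FALSE, bias_offset = 0) {
  if (!.is_number(center)) stop("`center` must be a number", call. = FALSE)
  if (!.is_number(force_constant) || force_constant < 0) {
    stop("`force_constant` must be a non-negative number", call. = FALSE)
  }
  if (!is.numeric(samples) || length(samples) == 0L ||
      !all(is.finite(samples))) {
    stop("`samples` must be a non-empty finite numeric vector",
         call. = FALSE)
  }
  if (!is.logical(half_k) || length(half_k) != 1L || is.na(half_k)) {
    stop("`half_k` must be TRUE or FALSE", call. = FALSE)
  }
  if (!.is_number(bias_offset)) {
    stop("`bias_offset` must be a number", call. = FALSE)
  }
  structure(
    list(center = center, force_constant = force_constant,
         samples = as.numeric(samples), half_k = half_k,
         bias_offset = bias_offset),
    class = "umbrella_window"
  )
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf(
    "<umbrella_window> center %.3f A, k %.1f kcal/mol/A^2%s, %d samples\n",
    x$center, x$force_constant, if (x$half_k) " (half-k)" else "",
    length(x$samples)))
  invisible(x)
}

# bias energy of a window evaluated at coordinates R
.bias_energy <- function(window, R) {
  pref <- if (window$half_k) 0.5 else 1
  pref * window$force_constant * (R - window$center)^2 + window$bias_offset
}

#' Read umbrella-window time series from text files
#'
#' One whitespace-delimited file per window; the last column of each row is
#' the sampled reaction-coordinate value R in angstrom (leading columns,
#' e.g. a time stamp, are ignored). Windows are returned sorted by bias
#' centre.
#'
#' @param paths character vector of file paths, one per window.
#' @param metadata data frame (or list coercible to one) with columns
#'   `center` and `force_constant`, one row per file, in the same order as
#'   `paths`.
#' @param half_k bias-prefactor convention of the recorded windows.
#' @return A list of [umbrella_window()] objects sorted by `center`.
#' @export
read_window_series <- function(paths, metadata, half_k = FALSE) {
  metadata <- as.data.frame(metadata)
  if (!all(c("center", "force_constant") %in% names(metadata))) {
    stop("`metadata` needs columns `center` and `force_constant`",
         call. = FALSE)
  }
  if (length(paths) != nrow(metadata)) {
    stop(sprintf(
      "count mismatch: %d window file(s) but metadata for %d window(s)",
      length(paths), nrow(metadata)), call. = FALSE)
  }
  windows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    if (!file.exists(paths[i])) {
      stop(sprintf("window file not found: %s", paths[i]), call. = FALSE)
    }
    lines <- readLines(paths[i])
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      stop(sprintf("empty window file: %s", paths[i]), call. = FALSE)
    }
    toks <- strsplit(trimws(lines), "\\s+")
    last <- vapply(toks, function(t) t[[length(t)]], character(1L))
    vals <- suppressWarnings(as.numeric(last))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("parse error in %s at line %d: '%s' is not numeric",
                   paths[i], bad, last[bad]), call. = FALSE)
    }
    windows[[i]] <- umbrella_window(metadata$center[i],
                                    metadata$force_constant[i],
                                    vals, half_k = half_k)
  }
  windows[order(vapply(windows, `[[`, numeric(1L), "center"))]
}

#' Write umbrella windows as time-series text files
#'
#' Emits one two-column file per window (`index R`), with R written at full
#' double precision, plus a metadata CSV (`file, center, force_constant,
#' n_samples, half_k`) that [read_window_series()] can consume.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the per-window files.
#' @return Invisibly, a list with the window file paths and the metadata
#'   path.
#' @export
write_window_series <- function(windows, dir, prefix = "window") {
  stopifnot(length(windows) > 0L,
            all(vapply(windows, inherits, logical(1L), "umbrella_window")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    paths[i] <- file.path(dir, sprintf("%s_%02d.dat", prefix, i))
    writeLines(sprintf("%d %.17g", seq_along(w$samples), w$samples),
               paths[i])
  }
  meta <- data.frame(
    file = basename(paths),
    center = vapply(windows, `[[`, numeric(1L), "center"),
    force_constant = vapply(windows, `[[`, numeric(1L), "force_constant"),
    n_samples = vapply(windows, function(w) length(w$samples), integer(1L)),
    half_k = vapply(windows, `[[`, logical(1L), "half_k")
  )
  meta_path <- file.path(dir, sprintf("%s_metadata.csv", prefix))
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(list(window_files = paths, metadata_file = meta_path))
}
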