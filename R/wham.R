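#' Uniform reaction-coordinate grid for PMF estimation
#'
#' @param min,max grid range on R, angstrom.
#' @param width bin width, angstrom.
#' @return A list with `breaks` and bin `centers`.
#' @export
wham_grid <- function(min = -2.5, max = 2.5, width = 0.05) {
  if (!.is_number(min) || !.is_number(max) || min >= max ||
      !.is_number(width) || width <= 0) {
    stop("invalid grid specification", call. = FALSE)
  }
  breaks <- seq(min, max, by = width)
  if (length(breaks) < 3L) stop("grid has fewer than two bins", call. = FALSE)
  list(breaks = breaks,
       centers = (breaks[-1L] + breaks[-length(breaks)]) / 2)
}

#' Construct a PMF profile from tabulated values
#'
#' Container for a potential of mean force on a uniform grid along the
#' reaction coordinate. [wham_solve()] produces these; the constructor also
#' lets tabulated or analytic profiles flow into [extract_barrier()] and
#' [apply_correction()].
#'
#' @param grid bin centres on R, angstrom, strictly increasing.
#' @param free_energy kcal/mol per bin; `NA` marks unsampled (masked) bins.
#' @param temperature kelvin.
#' @param window_shifts per-window free-energy constants f_i (gauge fixed at
#'   `f[1] = 0`), or `NULL`.
#' @param converged logical convergence flag.
#' @param iterations number of self-consistency iterations performed.
#' @param n_samples per-bin total sample counts, or `NULL`.
#' @export
pmf_profile <- function(grid, free_energy,
                        temperature = .default_temperature,
                        window_shifts = NULL, converged = NA,
                        iterations = NA_integer_, n_samples = NULL) {
  if (!is.numeric(grid) || any(!is.finite(grid)) || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing and finite", call. = FALSE)
  }
  if (length(free_energy) != length(grid)) {
    stop("`free_energy` must match `grid` in length", call. = FALSE)
  }
  .kT(temperature)
  structure(
    list(grid = as.numeric(grid), free_energy = as.numeric(free_energy),
         temperature = temperature, window_shifts = window_shifts,
         converged = converged, iterations = iterations,
         n_samples = n_samples),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  nd <- sum(!is.na(x$free_energy))
  cat(sprintf(
    "<pmf_profile> %d bins (%d defined) on [%.2f, %.2f] A, T = %.2f K\n",
    length(x$grid), nd, min(x$grid), max(x$grid), x$temperature))
  if (!is.na(x$converged) && !x$converged) {
    cat("  WARNING: WHAM did not converge\n")
  }
  invisible(x)
}

# anchor a free-energy vector so the reactant-side minimum is zero;
# falls back to the global minimum (with a warning) if that side is empty
.anchor_profile <- function(grid, fe, reactant_side) {
  defined <- !is.na(fe)
  side <- if (reactant_side == "negative") grid < 0 else grid > 0
  if (any(defined & side)) {
    fe - min(fe[defined & side])
  } else {
    warning("no defined bins on the reactant side; anchoring to the global minimum")
    fe - min(fe[defined])
  }
}

#' Estimate a potential of mean force by self-consistent WHAM
#'
#' Combines harmonically biased umbrella windows into one unbiased
#' free-energy profile along the reaction coordinate via the standard WHAM
#' self-consistency equations
#' \deqn{P(b) = \frac{\sum_i n_i(b)}{\sum_i N_i \exp[(f_i - w_i(b))/k_B T]},
#'   \qquad
#'   f_i = -k_B T \log \sum_b P(b) \exp[-w_i(b)/k_B T],}
#' iterated as a plain fixed point (no damping) until
#' `max |delta f_i| < tolerance` or the iteration cap is hit. All
#' accumulations run in log space, so arbitrarily strong biases do not
#' underflow. The profile `F(b) = -kB T log P(b)` is reported on bin
#' centres, masked where no window contributed a sample, and anchored so
#' the reactant-region minimum is zero. Non-convergence is reported
#' honestly: the profile is returned with `converged = FALSE` plus a
#' warning, never silently.
#'
#' All windows must share one bias-prefactor convention (see
#' [umbrella_window()]); mixing conventions is a hard error.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param temperature kelvin.
#' @param grid a [wham_grid()] (or compatible list with `breaks`).
#' @param tolerance convergence threshold on the window shifts, kcal/mol.
#' @param max_iterations iteration cap.
#' @param reactant_side `"negative"` (reactant at R < 0, the methyl still
#'   bonded to the donor sulfur — the convention here) or `"positive"`.
#' @param anchor `"reactant"` anchors the reactant-side minimum at zero;
#'   `"global"` anchors the overall minimum.
#' @return A [pmf_profile()].
#' @export
wham_solve <- function(windows, temperature = .default_temperature,
                       grid = wham_grid(), tolerance = 1e-6,
                       max_iterations = 1e5,
                       reactant_side = c("negative", "positive"),
                       anchor = c("reactant", "global")) {
  reactant_side <- match.arg(reactant_side)
  anchor <- match.arg(anchor)
  if (length(windows) < 1L ||
      !all(vapply(windows, inherits, logical(1L), "umbrella_window"))) {
    stop("`windows` must be a non-empty list of umbrella_window objects",
         call. = FALSE)
  }
  if (!.is_number(tolerance) || tolerance <= 0) {
    stop("`tolerance` must be positive", call. = FALSE)
  }
  if (!.is_count(max_iterations)) {
    stop("`max_iterations` must be a positive integer", call. = FALSE)
  }
  hk <- vapply(windows, `[[`, logical(1L), "half_k")
  if (length(unique(hk)) != 1L) {
    stop("bias-convention mismatch: windows mix half-k and full-k biases",
         call. = FALSE)
  }
  kT <- .kT(temperature)
  breaks <- grid$breaks
  centers <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  n_bins <- length(centers)
  n_win <- length(windows)

  # per-window histograms on the common grid
  counts <- matrix(0, n_win, n_bins)
  for (i in seq_len(n_win)) {
    idx <- .bin_index(windows[[i]]$samples, breaks)
    counts[i, ] <- tabulate(idx[!is.na(idx)], nbins = n_bins)
  }
  total <- colSums(counts)
  if (sum(total) == 0) {
    stop("no samples fall on the WHAM grid", call. = FALSE)
  }
  n_dropped <- sum(vapply(windows, function(w) length(w$samples),
                          numeric(1L))) - sum(total)
  if (n_dropped > 0) {
    warning(sprintf("%d sample(s) outside the WHAM grid were dropped",
                    n_dropped))
  }

  # adjacent-window overlap check on the sample ranges
  ord <- order(vapply(windows, `[[`, numeric(1L), "center"))
  for (k in seq_len(n_win - 1L)) {
    a <- windows[[ord[k]]]$samples
    b <- windows[[ord[k + 1L]]]$samples
    if (max(a) < min(b) || max(b) < min(a)) {
      warning(sprintf(
        "sample ranges of adjacent windows %d and %d (by center) are disjoint",
        k, k + 1L))
    }
  }

  defined <- total > 0
  cen_d <- centers[defined]
  logn_tot <- log(total[defined])
  N_i <- rowSums(counts)
  if (any(N_i == 0)) {
    warning("window(s) with no samples on the grid carry zero weight")
  }
  logN <- ifelse(N_i > 0, log(N_i), -Inf)
  # bias matrix over defined bins, in units of kT
  W <- t(vapply(windows, function(w) .bias_energy(w, cen_d) / kT,
                numeric(length(cen_d))))
  if (length(cen_d) == 1L) W <- matrix(W, nrow = n_win)

  f <- rep(0, n_win)          # window shifts in kcal/mol, gauge f[1] = 0
  iter <- 0L
  converged <- FALSE
  logP <- NULL
  repeat {
    iter <- iter + 1L
    # L[i, b] = log N_i + f_i/kT - W[i, b]
    L <- sweep(-W, 1L, logN + f / kT, `+`)
    m <- apply(L, 2L, max)
    logdenom <- m + log(colSums(exp(sweep(L, 2L, m, `-`))))
    logP <- logn_tot - logdenom
    # f_i <- -kT logsumexp_b (logP - W[i, ])
    M <- sweep(-W, 2L, logP, `+`)
    mm <- apply(M, 1L, max)
    f_new <- -kT * (mm + log(rowSums(exp(M - mm))))
    f_new <- f_new - f_new[1L]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) { converged <- TRUE; break }
    if (iter >= max_iterations) break
  }
  if (!converged) {
    warning(sprintf(
      "WHAM did not converge within %d iterations (last max|delta f| = %.3g kcal/mol)",
      as.integer(max_iterations), delta))
  }

  fe <- rep(NA_real_, n_bins)
  fe[defined] <- -kT * logP
  fe <- if (anchor == "reactant") {
    .anchor_profile(centers, fe, reactant_side)
  } else {
    fe - min(fe, na.rm = TRUE)
  }
  pmf_profile(centers, fe, temperature = temperature, window_shifts = f,
              converged = converged, iterations = iter, n_samples = total)
}

#' Barrier and stationary-point extraction from a PMF profile
#'
#' Reads off the forward free-energy barrier without smoothing: the
#' reactant state is the lowest defined bin on the reactant side, the
#' product state the lowest defined bin on the product side, and the
#' transition state the highest defined bin strictly between the two
#' minima. A profile
#' with no interior maximum (monotone) raises a no-barrier error. A run of
#' more than three consecutive masked bins between the reactant minimum and
#' the transition state triggers a data-quality warning (the search skips
#' masked bins but never interpolates across them).
#'
#' @param profile a [pmf_profile()].
#' @param reactant_side `"negative"` or `"positive"`: which side of R = 0
#'   holds the reactant minimum.
#' @return An object of class `barrier_result` with fields `barrier`
#'   (kcal/mol), `R_reactant`, `R_TS`, `F_TS`, `F_reactant`, `R_product`,
#'   `F_product`.
#' @export
extract_barrier <- function(profile,
                            reactant_side = c("negative", "positive")) {
  stopifnot(inherits(profile, "pmf_profile"))
  reactant_side <- match.arg(reactant_side)
  grid <- profile$grid
  fe <- profile$free_energy
  if (reactant_side == "positive") {    # mirror and reuse the forward scan
    grid <- rev(-grid)
    fe <- rev(fe)
  }
  def <- which(!is.na(fe))
  if (length(def) < 3L) {
    stop("no barrier: fewer than three defined bins", call. = FALSE)
  }
  react <- def[grid[def] < 0]
  if (length(react) == 0L) {
    stop("no defined bins on the reactant side", call. = FALSE)
  }
  i_r <- react[which.min(fe[react])]
  prod <- def[grid[def] > 0 & def > i_r]
  if (length(prod) == 0L) {
    stop("no barrier: no defined bins on the product side", call. = FALSE)
  }
  i_p <- prod[which.min(fe[prod])]
  between <- def[def > i_r & def < i_p]
  if (length(between) == 0L) {
    stop("no barrier: no interior bins between reactant and product minima",
         call. = FALSE)
  }
  i_ts <- between[which.max(fe[between])]
  if (!(fe[i_ts] > fe[i_r] && fe[i_ts] > fe[i_p])) {
    stop("no barrier: no interior maximum between reactant and product minima",
         call. = FALSE)
  }
  runs <- rle(is.na(fe[i_r:i_ts]))
  gap <- max(c(runs$lengths[runs$values], 0L))
  if (gap > 3L) {
    warning(sprintf(
      "coverage gap of %d consecutive empty bins between reactant and TS",
      gap))
  }
  sgn <- if (reactant_side == "positive") -1 else 1
  structure(
    list(barrier = fe[i_ts] - fe[i_r],
         R_reactant = sgn * grid[i_r], R_TS = sgn * grid[i_ts],
         F_TS = fe[i_ts], F_reactant = fe[i_r],
         R_product = sgn * grid[i_p], F_product = fe[i_p]),
    class = "barrier_result"
  )
}

#' @export
print.barrier_result <- function(x, ...) {
  cat(sprintf(
    "<barrier_result> %.2f kcal/mol (reactant R = %.2f A, TS R = %.2f A)\n",
    x$barrier, x$R_reactant, x$R_TS))
  invisible(x)
}

#' Empirical correction curve for a PMF
#'
#' A tabulated additive correction Delta-E(R), typically derived by
#' comparing a semi-empirical description of the methyl-transfer energetics
#' against a higher-level reference on a small model system. This package
#' only applies such curves; fitting one is the user's responsibility. The
#' default curve is identically zero.
#'
#' @param R knot positions, angstrom, strictly increasing; at least two.
#' @param delta_e correction values at the knots, kcal/mol.
#' @export
correction_curve <- function(R, delta_e) {
  if (!is.numeric(R) || length(R) < 2L || any(!is.finite(R)) ||
      any(diff(R) <= 0)) {
    stop("correction knots must be >= 2 strictly increasing R values",
         call. = FALSE)
  }
  if (length(delta_e) != length(R) || any(!is.finite(delta_e))) {
    stop("`delta_e` must be finite with one value per knot", call. = FALSE)
  }
  structure(list(R = as.numeric(R), delta_e = as.numeric(delta_e)),
            class = "correction_curve")
}

#' Read a correction curve from a two-column text/CSV file
#'
#' First column R (angstrom), second column Delta-E (kcal/mol); a header
#' row is detected automatically.
#'
#' @param path file path.
#' @return A [correction_curve()].
#' @export
read_correction_curve <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "[,[:space:]]+")[[1L]][1L])))
  tab <- utils::read.table(path, header = has_header,
                           sep = if (grepl(",", first)) "," else "")
  correction_curve(tab[[1L]], tab[[2L]])
}

#' Apply an empirical correction curve to a PMF profile
#'
#' Adds the correction, interpolated through the knots by a monotone cubic
#' (Fritsch-Carlson) spline, to every defined bin and re-anchors the
#' profile so the reactant-region minimum is zero. Extrapolation beyond the
#' knot span is forbidden.
#'
#' @param profile a [pmf_profile()].
#' @param curve a [correction_curve()], or `NULL` for the zero curve.
#' @param reactant_side orientation used for re-anchoring.
#' @return A corrected, re-anchored [pmf_profile()].
#' @export
apply_correction <- function(profile, curve = NULL,
                             reactant_side = c("negative", "positive")) {
  stopifnot(inherits(profile, "pmf_profile"))
  reactant_side <- match.arg(reactant_side)
  fe <- profile$free_energy
  defined <- which(!is.na(fe))
  if (length(defined) == 0L) stop("profile has no defined bins", call. = FALSE)
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "correction_curve"))
    rng <- range(profile$grid[defined])
    if (rng[1L] < min(curve$R) || rng[2L] > max(curve$R)) {
      stop(sprintf(
        "correction curve spans [%.3f, %.3f] but the profile needs [%.3f, %.3f]: extrapolation is forbidden",
        min(curve$R), max(curve$R), rng[1L], rng[2L]), call. = FALSE)
    }
    interp <- stats::splinefun(curve$R, curve$delta_e, method = "monoH.FC")
    fe[defined] <- fe[defined] + interp(profile$grid[defined])
  }
  fe <- .anchor_profile(profile$grid, fe, reactant_side)
  pmf_profile(profile$grid, fe, temperature = profile$temperature,
              window_shifts = profile$window_shifts,
              converged = profile$converged,
              iterations = profile$iterations,
              n_samples = profile$n_samples)
}

#' Bootstrap uncertainty for a WHAM profile
#'
#' Optional diagnostic: resamples each window's time series with
#' replacement, re-solves WHAM, and reports per-bin standard deviations and
#' the spread of the extracted barrier. Purely a precision estimate — the
#' point profile comes from [wham_solve()] on the original samples.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param n_boot number of resamples (default 50).
#' @param seed integer seed for the resampling.
#' @param ... passed to [wham_solve()] (and its defaults apply).
#' @return A list with `fe_sd` (per-bin SD, `NA` where any replicate was
#'   undefined), `barrier_sd`, and `barriers` (the replicate barriers;
#'   `NA` where extraction failed).
#' @export
wham_bootstrap <- function(windows, n_boot = 50, seed = 1, ...) {
  stopifnot(.is_count(n_boot))
  set.seed(seed)
  fes <- NULL
  barriers <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    res <- lapply(windows, function(w) {
      umbrella_window(w$center, w$force_constant,
                      sample(w$samples, length(w$samples), replace = TRUE),
                      half_k = w$half_k, bias_offset = w$bias_offset)
    })
    prof <- suppressWarnings(wham_solve(res, ...))
    if (is.null(fes)) {
      fes <- matrix(NA_real_, n_boot, length(prof$free_energy))
    }
    fes[b, ] <- prof$free_energy
    barriers[b] <- tryCatch(extract_barrier(prof)$barrier,
                            error = function(e) NA_real_)
  }
  list(fe_sd = apply(fes, 2L, stats::sd),
       barrier_sd = stats::sd(barriers, na.rm = TRUE),
       barriers = barriers)
}
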