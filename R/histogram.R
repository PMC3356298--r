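#' Default histogram bin edges for (r, theta) distributions
#'
#' r(CM..Nzeta) from 2 to 6 angstrom in 0.05-angstrom bins; theta from 0 to
#' 180 degrees in 5-degree bins. These match the visual granularity of
#' typical reactant-ensemble distribution plots and can be overridden
#' everywhere they are used.
#'
#' @name default_bins
#' @return Numeric vector of bin edges.
#' @export
default_r_edges <- function() seq(2, 6, by = 0.05)

#' @rdname default_bins
#' @export
default_theta_edges <- function() seq(0, 180, by = 5)

# bin assignment shared by every histogramming routine: half-open
# [low, high) bins, last bin closed, values on an interior edge go up.
# returns NA for out-of-range values.
.bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx >= length(edges)] <- NA_integer_
  idx
}

.check_edges <- function(edges, what) {
  if (!is.numeric(edges) || length(edges) < 2L || any(!is.finite(edges)) ||
      any(diff(edges) <= 0)) {
    stop(sprintf("`%s` must be strictly increasing bin edges", what),
         call. = FALSE)
  }
}

#' 2D histogram of (r, theta) geometry records
#'
#' Bins the acceptor distance r(CM..Nzeta) against the alignment angle
#' theta. Bins are half-open `[low, high)` with the last bin closed; a value
#' exactly on an interior edge is assigned to the higher bin. Records
#' outside the edge range are counted in `n_out_of_range` and not binned.
#'
#' @param records a `geometry_records` data frame from [compute_geometry()]
#'   (any data frame with columns `r_cn` and `theta` works).
#' @param r_edges,theta_edges strictly increasing bin edges.
#' @return An object of class `histogram2d` with fields `r_edges`,
#'   `theta_edges`, `counts` (r bins in rows), `n_total`, `n_out_of_range`.
#' @export
build_histogram2d <- function(records, r_edges = default_r_edges(),
                              theta_edges = default_theta_edges()) {
  if (!is.data.frame(records) ||
      !all(c("r_cn", "theta") %in% names(records))) {
    stop("`records` must have columns `r_cn` and `theta`", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("`records` is empty", call. = FALSE)
  .check_edges(r_edges, "r_edges")
  .check_edges(theta_edges, "theta_edges")

  ir <- .bin_index(records$r_cn, r_edges)
  it <- .bin_index(records$theta, theta_edges)
  keep <- !is.na(ir) & !is.na(it)
  n_out <- sum(!keep)
  if (!any(keep)) {
    stop("empty histogram: every record falls outside the bin ranges",
         call. = FALSE)
  }
  nr <- length(r_edges) - 1L
  nt <- length(theta_edges) - 1L
  counts <- matrix(
    tabulate((it[keep] - 1L) * nr + ir[keep], nbins = nr * nt),
    nrow = nr, ncol = nt)
  structure(
    list(r_edges = r_edges, theta_edges = theta_edges, counts = counts,
         n_total = sum(counts), n_out_of_range = n_out),
    class = "histogram2d"
  )
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf(
    "<histogram2d> %d x %d bins, %d record(s) binned, %d out of range\n",
    nrow(x$counts), ncol(x$counts), x$n_total, x$n_out_of_range))
  invisible(x)
}

# shared inversion core: counts -> free energy relative to the modal cell
.invert_counts <- function(counts, temperature) {
  kT <- .kT(temperature)
  fe <- counts
  fe[] <- NA_real_
  pos <- counts > 0
  fe[pos] <- -kT * log(counts[pos] / max(counts))
  fe
}

#' Boltzmann-invert a 2D histogram into a free-energy surface
#'
#' Converts binned occupancy into free energy per cell:
#' `F = -kB T log(count / count_max)` for occupied cells, so the modal cell
#' sits at exactly zero. Zero-count cells are masked (`NA`), never assigned
#' a pseudo-count.
#'
#' @param hist a [build_histogram2d()] result.
#' @param temperature kelvin.
#' @param pseudocount added to every cell before inversion, for plotting
#'   continuity only; the default 0 keeps empty cells masked and is what
#'   every quantitative use of the surface should run with.
#' @return An object of class `free_energy_surface` carrying the histogram
#'   grid, `free_energy` (kcal/mol, `NA` where unobserved), and
#'   `temperature`.
#' @export
boltzmann_invert <- function(hist, temperature = .default_temperature,
                             pseudocount = 0) {
  stopifnot(inherits(hist, "histogram2d"))
  if (hist$n_total <= 0L) stop("histogram has no counts", call. = FALSE)
  if (!.is_number(pseudocount) || pseudocount < 0) {
    stop("`pseudocount` must be >= 0", call. = FALSE)
  }
  counts <- hist$counts + pseudocount
  structure(
    list(r_edges = hist$r_edges, theta_edges = hist$theta_edges,
         counts = hist$counts,
         free_energy = .invert_counts(counts, temperature),
         temperature = temperature),
    class = "free_energy_surface"
  )
}

#' One-dimensional marginal free-energy profile
#'
#' Sums the 2D counts over the other axis and Boltzmann-inverts the
#' marginal, giving e.g. the free-energy change as a function of theta alone
#' (the cost of reaching the near-linear 0-15 degree alignment range is read
#' off this profile).
#'
#' @param hist a [build_histogram2d()] result.
#' @param axis `"r"` or `"theta"`: the axis to keep.
#' @param temperature kelvin.
#' @return A data frame with columns `center`, `lower`, `upper`, `count`,
#'   `free_energy` (kcal/mol, `NA` for empty bins; minimum over occupied
#'   bins is 0).
#' @export
marginal_free_energy <- function(hist, axis = c("r", "theta"),
                                 temperature = .default_temperature) {
  stopifnot(inherits(hist, "histogram2d"))
  axis <- match.arg(axis)
  counts <- if (axis == "r") rowSums(hist$counts) else colSums(hist$counts)
  edges <- if (axis == "r") hist$r_edges else hist$theta_edges
  data.frame(
    center = (edges[-1L] + edges[-length(edges)]) / 2,
    lower = edges[-length(edges)],
    upper = edges[-1L],
    count = counts,
    free_energy = as.numeric(.invert_counts(counts, temperature))
  )
}
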