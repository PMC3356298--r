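#' Draw umbrella-window samples from a model potential
#'
#' Window i draws `n_per_window` i.i.d. samples from the biased Boltzmann
#' density `p_i(R) ~ exp(-[U(R) + w_i(R)] / kB T)` with
#' `w_i(R) = k_i (R - c_i)^2` (or with the 1/2 prefactor under `half_k`).
#' Sampling is by inverse CDF on a dense uniform grid (4096 cells over the
#' potential's declared range, uniform within a cell), so the draw is the
#' exact target up to the grid discretisation, needs no integrator
#' parameters, and is bitwise reproducible given the seed.
#'
#' @param potential a [make_potential()] result.
#' @param centers bias centres, angstrom.
#' @param force_constants force constants, kcal/mol/A^2, one per centre.
#' @param n_per_window samples per window.
#' @param temperature kelvin.
#' @param seed integer seed; every call with the same arguments yields
#'   bitwise-identical samples.
#' @param half_k bias-prefactor convention recorded on the windows.
#' @param n_grid number of grid cells for the inverse CDF.
#' @return A list of [umbrella_window()] objects, one per centre, each with
#'   attributes `sample_mean` and `sample_var`.
#' @export
gen_umbrella_windows <- function(potential, centers, force_constants,
                                 n_per_window,
                                 temperature = .default_temperature,
                                 seed = 1, half_k = FALSE, n_grid = 4096) {
  stopifnot(inherits(potential, "model_potential"))
  if (length(centers) != length(force_constants)) {
    stop("`centers` and `force_constants` must have the same length",
         call. = FALSE)
  }
  if (!.is_count(n_per_window)) {
    stop("`n_per_window` must be a positive integer", call. = FALSE)
  }
  kT <- .kT(temperature)
  set.seed(seed)
  edges <- seq(potential$range[1L], potential$range[2L],
               length.out = n_grid + 1L)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  width <- diff(edges[1:2])
  U <- potential$U(mids)
  pref <- if (half_k) 0.5 else 1

  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    loge <- -(U + pref * force_constants[i] * (mids - centers[i])^2) / kT
    loge <- loge - max(loge)
    p <- exp(loge)
    cdf <- cumsum(p)
    cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(n_per_window)
    cell <- findInterval(u, c(0, cdf), rightmost.closed = TRUE)
    p_cell <- diff(c(0, cdf))
    frac <- (u - c(0, cdf)[cell]) / p_cell[cell]
    samples <- edges[cell] + frac * width
    w <- umbrella_window(centers[i], force_constants[i], samples,
                         half_k = half_k)
    attr(w, "sample_mean") <- mean(samples)
    attr(w, "sample_var") <- stats::var(samples)
    windows[[i]] <- w
  }
  windows
}

#' Default umbrella protocol for a double-well potential
#'
#' Twenty bias centres evenly spanning the two minima, with each window's
#' force constant set so the bias gradient dominates the local potential
#' gradient (`k_i = |U'(c_i)| / spacing`), clipped to the 50-400
#' kcal/mol/A^2 range used for methyl-transfer PMF simulations. Flat
#' regions get the softest allowed restraint and steep flanks a stiffer
#' one, keeping adjacent windows overlapping across the whole path.
#'
#' @param potential a double-well [make_potential()] result.
#' @param n_windows number of windows (default 20).
#' @param k_limits force-constant clip range, kcal/mol/A^2.
#' @return A list with `centers` and `force_constants`.
#' @export
umbrella_protocol <- function(potential, n_windows = 20,
                              k_limits = c(50, 400)) {
  stopifnot(inherits(potential, "model_potential"))
  if (is.na(potential$r_b)) {
    stop("the umbrella protocol needs a double-well potential", call. = FALSE)
  }
  centers <- seq(potential$r_a, potential$r_b, length.out = n_windows)
  spacing <- centers[2L] - centers[1L]
  h <- 1e-5
  grad <- abs((potential$U(centers + h) - potential$U(centers - h)) / (2 * h))
  k <- .clamp(grad / spacing, k_limits[1L], k_limits[2L])
  list(centers = centers, force_constants = k)
}

# truncated-normal draws by inverse CDF; sd = 0 degenerates to the mean
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate draw outside the truncation bounds", call. = FALSE)
    }
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi - plo < 0.01) {
    stop(sprintf(
      "infeasible ensemble spec: truncation to [%g, %g] rejects %.1f%% of N(%g, %g) draws",
      lower, upper, 100 * (1 - (phi - plo)), mean, sd), call. = FALSE)
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Specify a synthetic reactant-complex frame ensemble
#'
#' Target statistics for [gen_frames()]: per-frame draws of the acceptor
#' distance r(CM..Nzeta) and the alignment angle theta are truncated
#' normals (r > 1.5 angstrom, theta in 0-180 degrees), with the donor
#' distance r(CM..Sdelta) drawn around the S-C bond length. `methylation`
#' (0, 1 or 2 methyl groups already on N-zeta) controls which substituents
#' are placed on the nitrogen: the epsilon carbon plus two hydrogens, one
#' hydrogen and one methyl carbon, or two methyl carbons.
#'
#' @param n_frames number of frames.
#' @param mean_r,sd_r target mean and spread of r(CM..Nzeta), angstrom.
#' @param mean_theta,sd_theta target mean and spread of theta, degrees.
#' @param mean_r_cs,sd_r_cs donor-distance distribution, angstrom.
#' @param methylation 0, 1 or 2 methyl groups already on the acceptor.
#' @param seed integer seed.
#' @export
frame_ensemble_spec <- function(n_frames, mean_r = 3.0, sd_r = 0.15,
                                mean_theta = 30, sd_theta = 12,
                                mean_r_cs = 1.81, sd_r_cs = 0.02,
                                methylation = 0, seed = 1) {
  if (!.is_count(n_frames)) {
    stop("`n_frames` must be a positive integer", call. = FALSE)
  }
  if (!.is_number(mean_r) || mean_r <= 0 ||
      !.is_number(mean_theta) || mean_theta < 0 || mean_theta > 180 ||
      !.is_number(mean_r_cs) || mean_r_cs <= 0) {
    stop("ensemble means must lie in their physical ranges", call. = FALSE)
  }
  if (min(sd_r, sd_theta, sd_r_cs) < 0) {
    stop("ensemble spreads must be >= 0", call. = FALSE)
  }
  if (!methylation %in% 0:2) {
    stop("`methylation` must be 0, 1 or 2", call. = FALSE)
  }
  structure(
    list(n_frames = as.integer(n_frames), mean_r = mean_r, sd_r = sd_r,
         mean_theta = mean_theta, sd_theta = sd_theta,
         mean_r_cs = mean_r_cs, sd_r_cs = sd_r_cs,
         methylation = as.integer(methylation), seed = seed),
    class = "frame_ensemble_spec"
  )
}

#' Named ensemble presets
#'
#' `"reactive_wt_like"` emulates a reactive reactant complex — large
#' population at short acceptor distance and small alignment angle (mean
#' r(CM..Nzeta) 3.0 angstrom, mean theta 30 degrees).
#' `"nonreactive_wt3_like"` emulates the poorly aligned third-transfer
#' complex of a di-methyltransferase: long acceptor distance (mean 4.5
#' angstrom) and a broad, large-angle theta distribution, on a
#' di-methylated acceptor. Spreads are representative choices, not fitted
#' values.
#'
#' @param name preset name.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return A [frame_ensemble_spec()].
#' @export
frame_preset <- function(name = c("reactive_wt_like",
                                  "nonreactive_wt3_like"),
                         n_frames = 10000, seed = 1) {
  name <- match.arg(name)
  switch(name,
    reactive_wt_like = frame_ensemble_spec(
      n_frames, mean_r = 3.0, sd_r = 0.15, mean_theta = 30, sd_theta = 12,
      methylation = 0, seed = seed),
    nonreactive_wt3_like = frame_ensemble_spec(
      n_frames, mean_r = 4.5, sd_r = 0.30, mean_theta = 70, sd_theta = 30,
      methylation = 2, seed = seed))
}

# canonical regular tetrahedron directions; the first is the lone-pair
# (missing-vertex) direction, the rest the substituent bonds
.tet_vertex <- rbind(c( 1,  1,  1),
                     c( 1, -1, -1),
                     c(-1,  1, -1),
                     c(-1, -1,  1)) / sqrt(3)

# Rodrigues rotation matrix for unit axis and angle
.rotation_about <- function(axis, angle) {
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# rotation mapping unit vector a onto unit vector b
.rotation_between <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3L))
  if (d < -1 + 1e-12) {
    # pick any axis perpendicular to a
    ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .normalize(ref - sum(ref * a) * a)
    return(.rotation_about(axis, pi))
  }
  axis <- .normalize(c(a[2L] * b[3L] - a[3L] * b[2L],
                       a[3L] * b[1L] - a[1L] * b[3L],
                       a[1L] * b[2L] - a[2L] * b[1L]))
  .rotation_about(axis, acos(d))
}

#' Generate a synthetic frame ensemble with controlled (r, theta) statistics
#'
#' Builds labelled coordinate frames of the minimal SN2 centre (Sdelta, CM,
#' Nzeta and the three N-zeta substituents) whose per-frame geometry is
#' exactly the drawn values: Sdelta and CM sit on the attack axis at the
#' drawn donor distance, Nzeta at the drawn acceptor distance, and the
#' substituents form an ideal tetrahedral cap rotated so the lone-pair
#' direction makes exactly the drawn theta with the CM -> Sdelta vector,
#' then spun by a uniform random azimuth about that vector (theta is
#' azimuth-invariant). Running [compute_geometry()] on the output returns
#' each frame's drawn `(r_cn, r_cs, theta)` to better than 1e-6 — the
#' generator/analyzer closure that anchors the synthetic module.
#'
#' @param spec a [frame_ensemble_spec()] or [frame_preset()].
#' @param seed optional override of `spec$seed`.
#' @param temperature ensemble temperature recorded on the series, K.
#' @return A [frame_series()] with attribute `drawn` (data frame of the
#'   per-frame drawn `r_cn`, `r_cs`, `theta`).
#' @export
gen_frames <- function(spec, seed = NULL,
                       temperature = .default_temperature) {
  stopifnot(inherits(spec, "frame_ensemble_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  n <- spec$n_frames

  r_cn <- .rtruncnorm(n, spec$mean_r, spec$sd_r, lower = 1.5)
  r_cs <- .rtruncnorm(n, spec$mean_r_cs, spec$sd_r_cs, lower = 1.0)
  theta <- .rtruncnorm(n, spec$mean_theta, spec$sd_theta,
                       lower = 0, upper = 180)
  phi <- stats::runif(n, 0, 2 * pi)       # azimuth about the attack axis
  psi <- stats::runif(n, 0, 2 * pi)       # spin about the lone pair

  sub_names <- switch(as.character(spec$methylation),
                      "0" = c("CE", "HZ1", "HZ2"),
                      "1" = c("CE", "HZ1", "CH1"),
                      "2" = c("CE", "CH1", "CH2"))
  bond_len <- ifelse(substr(sub_names, 1L, 1L) == "H", 1.01, 1.49)
  atom_names <- c("SD", "CM", "NZ", sub_names)
  elements <- c("S", "C", "N", substr(sub_names, 1L, 1L))

  coords <- array(NA_real_, c(6L, 3L, n))
  t0 <- .tet_vertex[1L, ]
  b0 <- t(.tet_vertex[2:4, ])              # 3 x 3, columns = bond dirs
  for (f in seq_len(n)) {
    th <- theta[f] * pi / 180
    v <- c(cos(th), sin(th) * cos(phi[f]), sin(th) * sin(phi[f]))
    rot <- .rotation_between(t0, v) %*% .rotation_about(t0, psi[f])
    p_c <- c(0, 0, 0)
    p_s <- c(r_cs[f], 0, 0)
    p_n <- c(-r_cn[f], 0, 0)
    bonds <- rot %*% b0                    # columns are substituent dirs
    coords[1L, , f] <- p_s
    coords[2L, , f] <- p_c
    coords[3L, , f] <- p_n
    for (s in 1:3) {
      coords[3L + s, , f] <- p_n + bond_len[s] * bonds[, s]
    }
  }

  rm <- role_map("SD", "CM", "NZ", sub_names)
  fs <- frame_series(coords, atom_names, rm, temperature = temperature,
                     elements = elements)
  attr(fs, "drawn") <- data.frame(r_cn = r_cn, r_cs = r_cs, theta = theta)
  attr(fs, "spec") <- spec
  attr(fs, "seed") <- seed
  fs
}
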