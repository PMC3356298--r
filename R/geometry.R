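#' Lone-pair direction on the acceptor nitrogen
#'
#' For an sp3 nitrogen with three substituents the lone pair occupies the
#' missing tetrahedral vertex. The direction is constructed as
#' `u = -normalize(sum_i normalize(p_i - p_N))` over the three substituent
#' positions: exact for ideal sp3 geometry and robust to distortion. A
#' planar (or otherwise degenerate) nitrogen, where the three unit bond
#' vectors sum to nearly zero, has no defined lone-pair direction and raises
#' an error.
#'
#' @param fs a [frame_series()].
#' @param frame frame number (position in the series, default 1).
#' @return A unit 3-vector.
#' @export
lone_pair_direction <- function(fs, frame = 1L) {
  stopifnot(inherits(fs, "frame_series"))
  if (frame < 1L || frame > n_frames(fs)) {
    stop("`frame` out of range", call. = FALSE)
  }
  u <- .lone_pair_all(fs)
  u[frame, ]
}

# n_frames x 3 matrix of lone-pair unit vectors; vectorized across frames
.lone_pair_all <- function(fs) {
  p_n <- .role_coords(fs, "n_zeta")
  s <- matrix(0, nrow(p_n), 3L)
  for (k in c("sub1", "sub2", "sub3")) {
    b <- .role_coords(fs, k) - p_n
    nb <- .row_norms(b)
    if (any(nb < 1e-12)) {
      stop(sprintf(
        "degenerate geometry in frame %d: substituent coincides with N_zeta",
        fs$index[which(nb < 1e-12)[1L]]), call. = FALSE)
    }
    s <- s + b / nb
  }
  ns <- .row_norms(s)
  if (any(ns < 1e-8)) {
    stop(sprintf(
      "degenerate geometry in frame %d: planar nitrogen, lone-pair direction undefined",
      fs$index[which(ns < 1e-8)[1L]]), call. = FALSE)
  }
  -s / ns
}

#' Per-frame reactive-configuration statistics
#'
#' Computes, for every frame, the acceptor distance `r_cn = |CM - Nzeta|`,
#' the donor distance `r_cs = |CM - Sdelta|`, the SN2 reaction coordinate
#' `R = r_cs - r_cn`, and the alignment angle `theta` (degrees) between the
#' N-zeta lone-pair direction and the CM -> Sdelta vector. `theta = 0`
#' corresponds to perfect in-line SN2 alignment of the lone pair with the
#' donor methyl group; the reactant state (methyl still bonded to sulfur)
#' has `R < 0`.
#'
#' @param fs a [frame_series()].
#' @return A data frame of class `geometry_records` with columns `frame`,
#'   `r_cn`, `r_cs`, `R`, `theta`, in frame order.
#' @export
compute_geometry <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  p_s <- .role_coords(fs, "s_delta")
  p_c <- .role_coords(fs, "c_methyl")
  p_n <- .role_coords(fs, "n_zeta")
  r_cn <- .row_norms(p_c - p_n)
  r_cs <- .row_norms(p_c - p_s)
  if (any(r_cn < 1e-12) || any(r_cs < 1e-12)) {
    stop("degenerate geometry: coincident role atoms", call. = FALSE)
  }
  u <- .lone_pair_all(fs)
  v <- p_s - p_c
  nv <- .row_norms(v)
  cosang <- .clamp(rowSums(u * v) / nv, -1, 1)
  theta <- acos(cosang) * 180 / pi
  out <- data.frame(frame = fs$index, r_cn = r_cn, r_cs = r_cs,
                    R = r_cs - r_cn, theta = theta)
  class(out) <- c("geometry_records", "data.frame")
  out
}

#' Specify a geometric hydrogen-bond criterion
#'
#' A donor-acceptor pair satisfies the bond when the heavy-atom distance
#' D..A is at most `distance_cutoff` and, if a hydrogen selector is given,
#' the D-H..A angle (at the hydrogen) is at least `angle_cutoff`. The
#' defaults (3.5 angstrom, 120 degrees) are the common geometric criterion
#' for trajectory analysis.
#'
#' @param donor selector for the donor heavy atom.
#' @param acceptor selector for the acceptor heavy atom.
#' @param hydrogen optional selector for the donor hydrogen.
#' @param distance_cutoff maximum D..A distance, angstrom.
#' @param angle_cutoff minimum D-H..A angle, degrees.
#' @export
hbond_spec <- function(donor, acceptor, hydrogen = NULL,
                       distance_cutoff = 3.5, angle_cutoff = 120) {
  if (!.is_number(distance_cutoff) || distance_cutoff <= 0 ||
      !.is_number(angle_cutoff) || angle_cutoff <= 0) {
    stop("hydrogen-bond cutoffs must be positive", call. = FALSE)
  }
  structure(list(donor = donor, acceptor = acceptor, hydrogen = hydrogen,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_spec")
}

#' Hydrogen-bond occupancy over a frame series
#'
#' Fraction of frames in which the [hbond_spec()] criterion holds, e.g. for
#' the hydrogen bonds that an active-site tyrosine and water donate to the
#' target-lysine epsilon-amino group.
#'
#' @param fs a [frame_series()].
#' @param spec an [hbond_spec()].
#' @return A single number in `[0, 1]`.
#' @export
hbond_occupancy <- function(fs, spec) {
  stopifnot(inherits(fs, "frame_series"), inherits(spec, "hbond_spec"))
  n <- n_frames(fs)
  sel_coords <- function(selector, role) {
    out <- matrix(NA_real_, n, 3L)
    for (f in seq_len(n)) {
      rn <- if (is.null(fs$resnames)) NULL else fs$resnames[, f]
      idx <- .resolve_role(fs$atom_names[, f], rn, selector, role, 1L,
                           fs$index[f])
      out[f, ] <- fs$coords[idx, , f]
    }
    out
  }
  d <- sel_coords(spec$donor, "hbond donor")
  a <- sel_coords(spec$acceptor, "hbond acceptor")
  ok <- .row_norms(d - a) <= spec$distance_cutoff
  if (!is.null(spec$hydrogen)) {
    h <- sel_coords(spec$hydrogen, "hbond hydrogen")
    v1 <- d - h
    v2 <- a - h
    cosang <- .clamp(rowSums(v1 * v2) / (.row_norms(v1) * .row_norms(v2)),
                     -1, 1)
    ang <- acos(cosang) * 180 / pi
    ok <- ok & ang >= spec$angle_cutoff
  }
  sum(ok) / n
}
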