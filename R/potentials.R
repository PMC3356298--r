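#' Analytic model potential along the reaction coordinate
#'
#' Closed-form 1D potentials with exactly known stationary points and
#' barrier, used to generate synthetic umbrella data whose true free-energy
#' profile is known. Three forms:
#'
#' * `"harmonic"`: `U(R) = kappa/2 * R^2` (no barrier; useful for
#'   closed-form checks).
#' * `"quartic_double_well"`: the quartic whose derivative is
#'   `a (R - r_a)(R - r_t)(R - r_b)` — minima exactly at `r_a` (reactant)
#'   and `r_b` (product), maximum at `r_t`. Given the barrier `B` and the
#'   reactant-product offset `delta_rp`, the transition-state location is
#'   solved (the ratio `[U(r_b)-U(r_a)] / [U(r_t)-U(r_a)]` depends only on
#'   `r_t`) and the scale `a` then fixes `U(r_t) - U(r_a) = B` exactly.
#' * `"piecewise_cubic"`: two cubic Hermite segments through
#'   `(r_a, 0) -> (r_t, B) -> (r_b, delta_rp)` with zero slope at all three
#'   points, continued outside `[r_a, r_b]` by confining parabolas.
#'
#' `U(r_a) = 0` by construction in all double-well forms.
#'
#' @param form potential family.
#' @param barrier barrier height `U(r_t) - U(r_a)`, kcal/mol (> 0; a zero
#'   barrier violates the stationary-point ordering and is rejected).
#' @param r_a,r_b reactant and product minima, angstrom (`r_a < r_b`).
#' @param delta_rp product-minus-reactant free-energy offset, kcal/mol;
#'   must be `< barrier` (and the reverse barrier `barrier - delta_rp`
#'   positive).
#' @param kappa harmonic force constant, kcal/mol/A^2 (harmonic form only).
#' @param range sampling range on R; defaults to the minima padded by
#'   0.6 angstrom (harmonic: `[-3, 3]`).
#' @param wall_k confining-wall curvature for the piecewise form,
#'   kcal/mol/A^2.
#' @return An object of class `model_potential` with the evaluator `U`
#'   (vectorised, pure), the stationary points `r_a`, `r_t`, `r_b`, the
#'   programmed `barrier`, and the declared `range`.
#' @examples
#' p <- make_potential("quartic_double_well", barrier = 13.4,
#'                     r_a = -1.4, r_b = 1.2)
#' p$U(p$r_t) - p$U(p$r_a)   # exactly 13.4
#' @export
make_potential <- function(form = c("quartic_double_well", "harmonic",
                                    "piecewise_cubic"),
                           barrier = NULL, r_a = -1.4, r_b = 1.2,
                           delta_rp = 0, kappa = NULL, range = NULL,
                           wall_k = 50) {
  form <- match.arg(form)

  if (form == "harmonic") {
    if (!.is_number(kappa) || kappa <= 0) {
      stop("harmonic form needs `kappa` > 0", call. = FALSE)
    }
    if (is.null(range)) range <- c(-3, 3)
    return(structure(
      list(form = form, U = function(R) kappa / 2 * R^2,
           r_a = 0, r_t = NA_real_, r_b = NA_real_,
           barrier = NA_real_, delta_rp = NA_real_, kappa = kappa,
           range = range),
      class = "model_potential"))
  }

  if (!.is_number(barrier) || barrier <= 0) {
    stop("stationary-point ordering violated: `barrier` must be > 0",
         call. = FALSE)
  }
  if (!.is_number(r_a) || !.is_number(r_b) || r_a >= r_b) {
    stop("need r_a < r_b", call. = FALSE)
  }
  if (!.is_number(delta_rp) || delta_rp >= barrier) {
    stop("`delta_rp` must be smaller than the barrier (positive reverse barrier)",
         call. = FALSE)
  }
  if (is.null(range)) range <- c(r_a - 0.6, r_b + 0.6)

  if (form == "quartic_double_well") {
    # antiderivative of (s - r_a)(s - r_t)(s - r_b) as a function of r_t
    I <- function(x, r_t) {
      c2 <- -(r_a + r_t + r_b)
      c1 <- r_a * r_t + r_a * r_b + r_t * r_b
      c0 <- -r_a * r_t * r_b
      Q <- function(s) s^4 / 4 + c2 * s^3 / 3 + c1 * s^2 / 2 + c0 * s
      Q(x) - Q(r_a)
    }
    ratio <- delta_rp / barrier
    eps <- 1e-9 * (r_b - r_a)
    g <- function(r_t) I(r_b, r_t) / I(r_t, r_t) - ratio
    r_t <- stats::uniroot(g, c(r_a + eps, r_b - eps), tol = 1e-14)$root
    a <- barrier / I(r_t, r_t)
    if (!is.finite(a) || a <= 0) {
      stop("stationary-point ordering violated for the requested parameters",
           call. = FALSE)
    }
    U <- function(R) a * I(R, r_t)
    return(structure(
      list(form = form, U = U, r_a = r_a, r_t = r_t, r_b = r_b,
           barrier = barrier, delta_rp = delta_rp, kappa = NULL,
           range = range),
      class = "model_potential"))
  }

  # piecewise cubic Hermite with zero slopes at r_a, r_t, r_b
  r_t <- (r_a + r_b) / 2
  hermite <- function(R, x0, x1, y0, y1) {
    t <- (R - x0) / (x1 - x0)
    y0 * (2 * t^3 - 3 * t^2 + 1) + y1 * (-2 * t^3 + 3 * t^2)
  }
  U <- function(R) {
    out <- numeric(length(R))
    left <- R < r_a
    right <- R > r_b
    seg1 <- !left & !right & R <= r_t
    seg2 <- !left & !right & R > r_t
    out[seg1] <- hermite(R[seg1], r_a, r_t, 0, barrier)
    out[seg2] <- hermite(R[seg2], r_t, r_b, barrier, delta_rp)
    out[left] <- wall_k * (R[left] - r_a)^2
    out[right] <- delta_rp + wall_k * (R[right] - r_b)^2
    out
  }
  structure(
    list(form = form, U = U, r_a = r_a, r_t = r_t, r_b = r_b,
         barrier = barrier, delta_rp = delta_rp, kappa = NULL,
         range = range, wall_k = wall_k),
    class = "model_potential")
}

#' @export
print.model_potential <- function(x, ...) {
  if (x$form == "harmonic") {
    cat(sprintf("<model_potential> harmonic, kappa = %.3g kcal/mol/A^2\n",
                x$kappa))
  } else {
    cat(sprintf(
      "<model_potential> %s: minima %.3f / %.3f A, TS %.4f A, barrier %.3f kcal/mol\n",
      x$form, x$r_a, x$r_b, x$r_t, x$barrier))
  }
  invisible(x)
}
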