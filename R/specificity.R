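#' Per-step methyl-transfer barriers for one enzyme
#'
#' Ordered free-energy barriers for the successive methyl transfers
#' (lysine -> me1 -> me2 -> me3), at most three steps. A step the
#' simulations did not characterise is marked missing with `NA` and is
#' printed as `"x"`; it never silently becomes a number.
#'
#' @param enzyme enzyme label, e.g. `"WT"`.
#' @param barriers numeric vector of per-step barriers, kcal/mol, length 1
#'   to 3; use `NA` for a missing step.
#' @return An object of class `barrier_set`.
#' @examples
#' barrier_set("WT", c(13.4, 15.8, 22.1))
#' barrier_set("F1209Y", c(13.8, 17.4, NA))
#' @export
barrier_set <- function(enzyme, barriers) {
  if (!is.character(enzyme) || length(enzyme) != 1L || !nzchar(enzyme)) {
    stop("`enzyme` must be one non-empty string", call. = FALSE)
  }
  if (!is.numeric(barriers) || length(barriers) < 1L ||
      length(barriers) > 3L) {
    stop("`barriers` must be 1 to 3 per-step values", call. = FALSE)
  }
  if (any(!is.na(barriers) & !is.finite(barriers))) {
    stop("present barriers must be finite", call. = FALSE)
  }
  # trailing NAs are permitted (untried steps); interior gaps are not
  present <- which(!is.na(barriers))
  if (length(present) == 0L) {
    stop("at least one step barrier must be present", call. = FALSE)
  }
  if (any(diff(present) != 1L) || present[1L] != 1L) {
    stop("missing steps must be trailing (step 1..k present, rest NA)",
         call. = FALSE)
  }
  structure(list(enzyme = enzyme, barriers = as.numeric(barriers),
                 n_steps = length(present)),
            class = "barrier_set")
}

#' @export
print.barrier_set <- function(x, ...) {
  cat(sprintf("<barrier_set> %s: %s kcal/mol\n", x$enzyme,
              paste(.fmt1(x$barriers), collapse = ", ")))
  invisible(x)
}

# 1-decimal formatting with "x" for missing, matching how triplets are
# conventionally reported
.fmt1 <- function(x) ifelse(is.na(x), "x", sprintf("%.1f", x))

#' Read per-step barrier sets from a CSV file
#'
#' Expects columns `enzyme`, `step`, `barrier` (kcal/mol).
#'
#' @param path file path.
#' @return A named list of [barrier_set()] objects.
#' @export
read_barriers <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path)
  if (!all(c("enzyme", "step", "barrier") %in% names(tab))) {
    stop("barrier CSV needs columns enzyme, step, barrier", call. = FALSE)
  }
  out <- lapply(split(tab, tab$enzyme), function(d) {
    b <- rep(NA_real_, max(d$step))
    b[d$step] <- d$barrier
    barrier_set(as.character(d$enzyme[1L]), b)
  })
  out[unique(as.character(tab$enzyme))]
}

#' Free-energy triplet of an enzyme relative to the wild type
#'
#' Summarises the energetics of successive methyl transfers as three
#' numbers referenced to the wild-type first-transfer barrier: element j is
#' `(enzyme barrier for step j) - (WT step-1 barrier)`, so the wild type's
#' own triplet starts with an exact 0 and a mutant's first element is the
#' shift of its first barrier. Alongside, the within-enzyme deltas
#' `(barrier_j - barrier_1)` — each enzyme against its own first step, the
#' quantity the specificity call uses — are reported. Missing steps
#' propagate as marked-missing (`NA`, printed `"x"`).
#'
#' @param wt [barrier_set()] for the wild-type enzyme; step 1 must be
#'   present.
#' @param enzyme [barrier_set()] for the enzyme of interest (may be `wt`
#'   itself).
#' @return An object of class `triplet_result` with fields `enzyme`,
#'   `triplet`, `within_enzyme_deltas` (both length 3, `NA` = missing) and
#'   `wt_reference`.
#' @examples
#' wt <- barrier_set("WT", c(13.4, 15.8, 22.1))
#' compute_triplet(wt, wt)                         # (0.0, 2.4, 8.7)
#' compute_triplet(wt, barrier_set("F1209Y", c(13.8, 17.4, NA)))
#' @export
compute_triplet <- function(wt, enzyme) {
  stopifnot(inherits(wt, "barrier_set"), inherits(enzyme, "barrier_set"))
  if (is.na(wt$barriers[1L])) {
    stop("the wild-type set must contain a step-1 barrier", call. = FALSE)
  }
  b <- c(enzyme$barriers, rep(NA_real_, 3L - length(enzyme$barriers)))
  triplet <- b - wt$barriers[1L]
  if (identical(enzyme$enzyme, wt$enzyme)) triplet[1L] <- 0  # exact zero
  within <- b - b[1L]
  structure(
    list(enzyme = enzyme$enzyme, triplet = triplet,
         within_enzyme_deltas = within, wt_reference = wt$barriers[1L]),
    class = "triplet_result"
  )
}

#' @export
print.triplet_result <- function(x, ...) {
  cat(sprintf("<triplet_result> %s\n", x$enzyme))
  cat(sprintf("  triplet (vs WT step 1):     (%s)\n",
              paste(.fmt1(x$triplet), collapse = ", ")))
  cat(sprintf("  within-enzyme deltas:       (%s)\n",
              paste(.fmt1(x$within_enzyme_deltas), collapse = ", ")))
  invisible(x)
}

#' Format a triplet at one decimal
#'
#' @param x a `triplet_result`.
#' @param which `"triplet"` or `"within"`.
#' @return Character vector of length 3, missing entries as `"x"`.
#' @export
format_triplet <- function(x, which = c("triplet", "within")) {
  stopifnot(inherits(x, "triplet_result"))
  which <- match.arg(which)
  .fmt1(if (which == "triplet") x$triplet else x$within_enzyme_deltas)
}

#' Product-specificity call from per-step barriers
#'
#' A relatively high barrier for a later methyl transfer stops further
#' methyl addition. Scanning steps 2 then 3, the first step whose
#' within-enzyme delta `(barrier_j - barrier_1)` reaches the threshold
#' blocks the process: blocked at step 2 means a mono-methyltransferase,
#' blocked at step 3 a di-methyltransferase, no block across three present
#' steps a tri-methyltransferase. When the set ends before step 3 without a
#' block, the call is the state reachable from the present steps and
#' `undetermined_beyond` records the last characterised step — a missing
#' step never silently blocks or passes.
#'
#' @param enzyme a [barrier_set()]; step 1 must be present.
#' @param threshold blocking threshold, kcal/mol (default 3.0).
#' @return An object of class `specificity_call` with fields `enzyme`,
#'   `call` (`"mono"`, `"di"` or `"tri"`), `threshold`, `blocking_step`
#'   (2, 3 or `NA`) and `undetermined_beyond` (last present step, or `NA`
#'   when the call is fully determined).
#' @examples
#' classify_specificity(barrier_set("WT", c(13.4, 15.8, 22.1)))      # di
#' classify_specificity(barrier_set("F1209Y", c(13.8, 17.4)))        # mono
#' classify_specificity(barrier_set("Y1124F", c(13.9, 15.9, 13.3)))  # tri
#' @export
classify_specificity <- function(enzyme, threshold = 3.0) {
  stopifnot(inherits(enzyme, "barrier_set"))
  if (!.is_number(threshold) || threshold <= 0) {
    stop("`threshold` must be a positive number (kcal/mol)", call. = FALSE)
  }
  b <- enzyme$barriers
  if (is.na(b[1L])) {
    stop("step-1 barrier must be present for classification", call. = FALSE)
  }
  calls <- c("mono", "di", "tri")
  blocking <- NA_integer_
  for (j in 2:3) {
    if (j <= length(b) && !is.na(b[j])) {
      if (b[j] - b[1L] >= threshold) { blocking <- j; break }
    } else {
      break
    }
  }
  if (!is.na(blocking)) {
    call <- calls[blocking - 1L]
    undetermined <- NA_integer_
  } else {
    k <- enzyme$n_steps
    call <- calls[k]
    undetermined <- if (k < 3L) k else NA_integer_
  }
  structure(
    list(enzyme = enzyme$enzyme, call = call, threshold = threshold,
         blocking_step = blocking, undetermined_beyond = undetermined),
    class = "specificity_call"
  )
}

#' @export
print.specificity_call <- function(x, ...) {
  extra <- if (!is.na(x$blocking_step)) {
    sprintf(" (blocked at step %d)", x$blocking_step)
  } else if (!is.na(x$undetermined_beyond)) {
    sprintf(" (undetermined beyond step %d)", x$undetermined_beyond)
  } else ""
  cat(sprintf("<specificity_call> %s: %s at threshold %.1f kcal/mol%s\n",
              x$enzyme, x$call, x$threshold, extra))
  invisible(x)
}

#' Threshold consistency band for a set of specificity calls
#'
#' Diagnostic for the blocking threshold: given enzymes and their expected
#' calls, returns the interval of thresholds over which every call holds
#' under the within-enzyme-delta rule. Each expected call constrains the
#' threshold t as: `mono` needs `t <= delta_2`; `di` needs
#' `delta_2 < t` and (when step 3 is present) `t <= delta_3`; `tri` needs
#' `t > max(delta_2, delta_3)`. The band is the intersection, open at the
#' lower end and closed at the upper end (blocking uses `>=`).
#'
#' @param barrier_sets list of [barrier_set()] objects.
#' @param expected_calls character vector of `"mono"`/`"di"`/`"tri"`, one
#'   per set.
#' @return A list with `lower`, `upper` (possibly `Inf`), `empty`
#'   (logical), and the per-enzyme constraint table `constraints`.
#' @export
specificity_threshold_band <- function(barrier_sets, expected_calls) {
  stopifnot(length(barrier_sets) == length(expected_calls),
            all(expected_calls %in% c("mono", "di", "tri")))
  lower <- 0
  upper <- Inf
  rows <- list()
  for (i in seq_along(barrier_sets)) {
    bs <- barrier_sets[[i]]
    b <- bs$barriers
    d2 <- if (length(b) >= 2L) b[2L] - b[1L] else NA_real_
    d3 <- if (length(b) >= 3L) b[3L] - b[1L] else NA_real_
    lo <- 0; hi <- Inf
    switch(expected_calls[i],
      mono = {
        if (is.na(d2)) stop(sprintf(
          "'%s': a mono call needs a step-2 barrier", bs$enzyme),
          call. = FALSE)
        hi <- d2
      },
      di = {
        if (is.na(d2)) stop(sprintf(
          "'%s': a di call needs a step-2 barrier", bs$enzyme),
          call. = FALSE)
        lo <- d2
        if (!is.na(d3)) hi <- d3
      },
      tri = {
        if (is.na(d2) || is.na(d3)) stop(sprintf(
          "'%s': a tri call needs all three barriers", bs$enzyme),
          call. = FALSE)
        lo <- max(d2, d3)
      })
    lower <- max(lower, lo)
    upper <- min(upper, hi)
    rows[[i]] <- data.frame(enzyme = bs$enzyme, call = expected_calls[i],
                            lower = lo, upper = hi)
  }
  list(lower = lower, upper = upper, empty = !(lower < upper),
       constraints = do.call(rbind, rows))
}
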