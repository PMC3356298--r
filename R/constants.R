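# Global unit conventions: angstrom, kcal/mol, degrees, kelvin.

# Boltzmann constant, kcal mol^-1 K^-1
.kB <- 1.987204259e-3

# Default simulation temperature, K
.default_temperature <- 283.15

.kT <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive number (kelvin)",
         call. = FALSE)
  }
  .kB * temperature
}

.vnorm <- function(v) sqrt(sum(v * v))

.normalize <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

# row-wise euclidean norms of an n x 3 matrix
.row_norms <- function(m) sqrt(rowSums(m * m))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log(sum(exp(x))) guarded against overflow; x may contain -Inf
.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
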